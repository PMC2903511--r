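#' Create a physiological compartment
#'
#' A compartment is one node of the chemical-independent whole-body network:
#' a tissue (or tissue lump) with a volume, a blood perfusion rate and a
#' mass-balance scheme. Storage compartments (bone shells, gut lumen, hair)
#' exchange material through explicit transport processes rather than
#' perfusion and are excluded from the cardiac-output budget, as is the
#' central blood pool itself.
#'
#' @param name Unique compartment name.
#' @param volume Tissue volume (L); must be positive.
#' @param blood_flow Perfusion rate (L/h); zero for storage compartments.
#' @param scheme One of `"perfusion_limited"`, `"diffusion_limited"`,
#'   `"storage"`.
#' @param subvolumes For diffusion-limited tissues, a numeric vector
#'   `c(extracellular, cellular)` in L summing to `volume`.
#' @param tags Character vector of role tags (e.g. `"liver"`, `"blood"`,
#'   `"rapidly_perfused"`); used by [lump_compartments()] to classify
#'   tissues into rapidly/slowly perfused lumps.
#' @return A `compartment` object (list).
#' @export
compartment <- function(name, volume, blood_flow = 0,
                        scheme = c("perfusion_limited", "diffusion_limited", "storage"),
                        subvolumes = NULL, tags = character()) {
  scheme <- match.arg(scheme)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("compartment 'name' must be a non-empty string")
  if (!is.numeric(volume) || length(volume) != 1L || !is.finite(volume) || volume <= 0)
    stop(sprintf("compartment '%s': 'volume' must be a positive number (L)", name))
  if (!is.numeric(blood_flow) || length(blood_flow) != 1L || !is.finite(blood_flow) || blood_flow < 0)
    stop(sprintf("compartment '%s': 'blood_flow' must be >= 0 (L/h)", name))
  if (scheme == "diffusion_limited") {
    if (is.null(subvolumes) || length(subvolumes) != 2L || any(subvolumes <= 0))
      stop(sprintf("compartment '%s': diffusion-limited tissues need subvolumes c(extracellular, cellular) > 0", name))
    if (abs(sum(subvolumes) - volume) > 1e-9 * volume)
      stop(sprintf("compartment '%s': extracellular + cellular subvolumes must equal volume", name))
    subvolumes <- as.numeric(subvolumes)
    names(subvolumes) <- c("extracellular", "cellular")
  } else {
    subvolumes <- NULL
  }
  structure(list(name = name, volume = volume, blood_flow = blood_flow,
                 scheme = scheme, subvolumes = subvolumes,
                 tags = unique(as.character(tags))),
            class = "compartment")
}

#' Assemble a whole-body physiology
#'
#' Collects compartments into a validated chemical-independent body:
#' perfused tissue flows must sum exactly to cardiac output, names must be
#' unique, and the total tissue volume cannot exceed what the body mass
#' implies (taking tissue density as ~1 kg/L).
#'
#' @param compartments List of [compartment()] objects.
#' @param cardiac_output Total blood flow leaving the heart (L/h).
#' @param body_mass Body mass (kg).
#' @param lumps Optional named list recording lump membership
#'   (`lump_name -> character vector of merged tissue names`).
#' @return A validated `body_physiology` object.
#' @export
body_physiology <- function(compartments, cardiac_output, body_mass, lumps = list()) {
  body <- structure(list(compartments = compartments,
                         cardiac_output = cardiac_output,
                         body_mass = body_mass,
                         lumps = lumps),
                    class = "body_physiology")
  validate_body(body)
}

# Perfused compartments are those that count against cardiac output:
# non-storage, and not the central blood pool.
perfused_names <- function(body) {
  keep <- vapply(body$compartments, function(cp) {
    cp$scheme != "storage" && !("blood" %in% cp$tags)
  }, logical(1))
  vapply(body$compartments[keep], `[[`, character(1), "name")
}

#' Validate a body physiology
#'
#' Checks the physiological-consistency invariants: unique compartment
#' names, positive volumes, non-negative flows, perfused flows summing to
#' cardiac output (relative tolerance 1e-9), and total volume bounded by
#' body mass.
#'
#' @param body A `body_physiology` object.
#' @return The validated body, invisibly usable in pipelines.
#' @export
validate_body <- function(body) {
  if (!inherits(body, "body_physiology")) stop("not a body_physiology object")
  if (is.null(body$cardiac_output) || !is.finite(body$cardiac_output) || body$cardiac_output <= 0)
    stop("missing or non-positive 'cardiac_output'")
  if (is.null(body$body_mass) || !is.finite(body$body_mass) || body$body_mass <= 0)
    stop("missing or non-positive 'body_mass'")
  nm <- vapply(body$compartments, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate compartment names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  for (cp in body$compartments) {
    if (!inherits(cp, "compartment")) stop("compartments must be 'compartment' objects")
  }
  pn <- perfused_names(body)
  qsum <- sum(vapply(body$compartments[match(pn, nm)], `[[`, numeric(1), "blood_flow"))
  if (abs(qsum - body$cardiac_output) > 1e-9 * body$cardiac_output)
    stop(sprintf("flow conservation violated: perfused flows sum to %.6g L/h but cardiac_output is %.6g L/h",
                 qsum, body$cardiac_output))
  vtot <- sum(vapply(body$compartments, `[[`, numeric(1), "volume"))
  if (vtot > body$body_mass * 1.05)  # ~1 kg/L tissue density with 5% slack
    stop(sprintf("total compartment volume %.3g L exceeds body-mass-implied volume (%.3g kg)",
                 vtot, body$body_mass))
  body
}

#' @export
print.body_physiology <- function(x, ...) {
  cat(sprintf("body_physiology: %d compartments, cardiac output %.1f L/h, body mass %.1f kg\n",
              length(x$compartments), x$cardiac_output, x$body_mass))
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.body_physiology <- function(x, ...) {
  data.frame(
    name = vapply(x$compartments, `[[`, character(1), "name"),
    volume_L = vapply(x$compartments, `[[`, numeric(1), "volume"),
    blood_flow_L_h = vapply(x$compartments, `[[`, numeric(1), "blood_flow"),
    scheme = vapply(x$compartments, `[[`, character(1), "scheme"),
    tags = vapply(x$compartments, function(cp) paste(cp$tags, collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
}

get_compartment <- function(body, name) {
  nm <- vapply(body$compartments, `[[`, character(1), "name")
  i <- match(name, nm)
  if (is.na(i)) stop(sprintf("unknown compartment '%s'", name))
  body$compartments[[i]]
}

#' Load a body physiology from a description file or list
#'
#' Reads a YAML or JSON physiology description with fields
#' `cardiac_output` (L/h), `body_mass` (kg) and `compartments`
#' (each with `name`, `volume`, `blood_flow`, `scheme`, optional
#' `subvolumes` and `tags`), validates it and returns a
#' `body_physiology`. Validation errors name the offending field.
#'
#' @param spec Path to a `.yaml`/`.yml`/`.json` file, or an equivalent list.
#' @return A validated `body_physiology`.
#' @export
load_physiology <- function(spec) {
  if (is.character(spec) && length(spec) == 1L) {
    if (!file.exists(spec)) stop(sprintf("physiology file not found: %s", spec))
    spec <- if (grepl("\\.json$", spec)) jsonlite::read_json(spec, simplifyVector = FALSE)
            else yaml::read_yaml(spec)
  }
  if (!is.list(spec)) stop("physiology spec must be a file path or a list")
  if (is.null(spec$cardiac_output)) stop("physiology spec: missing 'cardiac_output'")
  if (is.null(spec$body_mass)) stop("physiology spec: missing 'body_mass'")
  if (is.null(spec$compartments) || !length(spec$compartments))
    stop("physiology spec: missing 'compartments'")
  comps <- lapply(spec$compartments, function(cs) {
    if (is.null(cs$name)) stop("physiology spec: compartment without 'name'")
    compartment(name = cs$name,
                volume = if (is.null(cs$volume)) stop(sprintf("compartment '%s': missing 'volume'", cs$name)) else cs$volume,
                blood_flow = if (is.null(cs$blood_flow)) 0 else cs$blood_flow,
                scheme = if (is.null(cs$scheme)) "perfusion_limited" else cs$scheme,
                subvolumes = if (is.null(cs$subvolumes)) NULL else unlist(cs$subvolumes),
                tags = if (is.null(cs$tags)) character() else unlist(cs$tags))
  })
  body_physiology(comps, cardiac_output = spec$cardiac_output,
                  body_mass = spec$body_mass)
}

#' Packaged reference adult physiology
#'
#' Loads the packaged reference adult body (70 kg, cardiac output 312 L/h,
#' the standard explicit tissue set plus rapidly/slowly perfused remainders
#' and gut-lumen storage). These are package defaults in standard
#' physiological ranges, shared by every chemical-specific model builder so
#' that all chemicals see one consistent body.
#'
#' @return A validated `body_physiology`.
#' @export
reference_adult <- function() {
  load_physiology(system.file("extdata", "physiology_adult.yaml", package = "pbtkmix"))
}

# default rapid/slow classification by role tags; editable via the
# `classification` argument of lump_compartments()
default_lump_classes <- function() {
  list(
    rapidly_perfused = c("liver", "kidney", "brain", "gut", "heart", "lung",
                         "viscera", "rapidly_perfused"),
    slowly_perfused  = c("muscle", "skin", "fat", "bone", "slowly_perfused")
  )
}

#' Lump non-explicit tissues into rapidly/slowly perfused groups
#'
#' Tissues not listed in `explicit` (and not blood or storage) are merged
#' into rapidly- and slowly-perfused lumps according to their role tags.
#' The combined lump flow is constrained to equal cardiac output minus the
#' explicit flows, so overall physiological consistency is maintained
#' exactly; lump volumes are the sums of member volumes. Applying the
#' operation twice with the same explicit set is a no-op.
#'
#' @param body A `body_physiology`.
#' @param explicit Character vector of compartment names kept explicit.
#' @param classification Named list mapping lump name to the role tags it
#'   absorbs; defaults to the packaged rapid/slow table.
#' @return A new validated `body_physiology` with `lumps` recording
#'   membership.
#' @export
lump_compartments <- function(body, explicit, classification = default_lump_classes()) {
  nm <- vapply(body$compartments, `[[`, character(1), "name")
  bad <- setdiff(explicit, nm)
  if (length(bad)) stop("unknown compartments in 'explicit': ", paste(bad, collapse = ", "))
  keep <- vapply(body$compartments, function(cp) {
    cp$name %in% explicit || cp$scheme == "storage" || "blood" %in% cp$tags
  }, logical(1))
  to_lump <- body$compartments[!keep]
  if (!length(to_lump)) {
    body$lumps <- lapply(body$lumps, identity)
    return(validate_body(body))
  }
  q_explicit <- sum(vapply(body$compartments[keep], function(cp) {
    if (cp$scheme == "storage" || "blood" %in% cp$tags) 0 else cp$blood_flow
  }, numeric(1)))
  q_budget <- body$cardiac_output - q_explicit
  if (q_budget < -1e-9 * body$cardiac_output)
    stop(sprintf("explicit flows (%.6g L/h) exceed cardiac output (%.6g L/h)",
                 q_explicit, body$cardiac_output))
  assign_class <- function(cp) {
    for (cls in names(classification)) {
      if (length(intersect(cp$tags, classification[[cls]]))) return(cls)
    }
    names(classification)[length(classification)]  # default: last (slow) class
  }
  cls <- vapply(to_lump, assign_class, character(1))
  groups <- split(to_lump, cls)
  q_members <- sum(vapply(to_lump, `[[`, numeric(1), "blood_flow"))
  if (q_members <= 0) stop("tissues to lump carry zero total flow; cannot allocate lump flow")
  scale <- q_budget / q_members   # exact cardiac-output closure
  lump_comps <- lapply(names(groups), function(g) {
    members <- groups[[g]]
    compartment(name = g,
                volume = sum(vapply(members, `[[`, numeric(1), "volume")),
                blood_flow = scale * sum(vapply(members, `[[`, numeric(1), "blood_flow")),
                scheme = "perfusion_limited",
                tags = c(g, "lump"))
  })
  lumps <- body$lumps
  for (g in names(groups)) {
    lumps[[g]] <- unique(c(lumps[[g]],
                           unlist(lapply(groups[[g]], function(cp) {
                             if ("lump" %in% cp$tags && !is.null(body$lumps[[cp$name]]))
                               body$lumps[[cp$name]] else cp$name
                           }))))
  }
  body$compartments <- c(body$compartments[keep], lump_comps)
  body$lumps <- lumps
  validate_body(body)
}

#' Sample a virtual individual
#'
#' Perturbs volumes, flows and cardiac output lognormally around the base
#' body with the requested coefficients of variation, then renormalizes
#' perfused flows so they sum exactly to the sampled cardiac output. The
#' lognormal is parameterized to preserve the mean and hit the requested
#' CV. Deterministic given `seed`; `cv = 0` returns the base body
#' unchanged. The result always passes validation.
#'
#' @param base A `body_physiology`.
#' @param cv_spec Named list of coefficients of variation; recognized
#'   fields: `volume`, `blood_flow`, `cardiac_output`, `body_mass`
#'   (defaults 0).
#' @param seed Integer seed.
#' @return A validated `body_physiology`.
#' @export
sample_individual <- function(base, cv_spec = list(), seed = 1L) {
  cv <- function(field) {
    v <- cv_spec[[field]]
    if (is.null(v)) 0 else v
  }
  for (f in names(cv_spec)) {
    if (cv_spec[[f]] < 0) stop(sprintf("cv_spec$%s must be >= 0", f))
  }
  draw <- function(x, cvv) {
    if (cvv == 0) return(x)
    sdl <- sqrt(log(1 + cvv^2))
    stats::rlnorm(length(x), meanlog = log(x) - sdl^2 / 2, sdlog = sdl)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  body <- base
  body$cardiac_output <- draw(base$cardiac_output, cv("cardiac_output"))
  body$body_mass <- draw(base$body_mass, cv("body_mass"))
  vtot_base <- sum(vapply(base$compartments, `[[`, numeric(1), "volume"))
  body$compartments <- lapply(base$compartments, function(cp) {
    v <- draw(cp$volume, cv("volume"))
    if (!is.null(cp$subvolumes)) {
      cp$subvolumes <- cp$subvolumes * (v / cp$volume)
    }
    cp$volume <- v
    if (cp$blood_flow > 0) cp$blood_flow <- draw(cp$blood_flow, cv("blood_flow"))
    cp
  })
  # tissue mass moves with sampled tissue volume (~1 kg/L), keeping the
  # volume <= body-mass invariant; cv = 0 leaves everything untouched
  vtot_new <- sum(vapply(body$compartments, `[[`, numeric(1), "volume"))
  body$body_mass <- body$body_mass + (vtot_new - vtot_base)
  nm <- vapply(body$compartments, `[[`, character(1), "name")
  pn <- perfused_names(body)
  qsum <- sum(vapply(body$compartments[match(pn, nm)], `[[`, numeric(1), "blood_flow"))
  scale <- body$cardiac_output / qsum
  body$compartments <- lapply(body$compartments, function(cp) {
    if (cp$name %in% pn) cp$blood_flow <- cp$blood_flow * scale
    cp
  })
  validate_body(body)
}
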