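# Assembly of the multi-chemical whole-body ODE system.
#
# The full state vector is [amounts | interaction effects | ledgers].
# Everything except Michaelis-Menten metabolism is linear in the state, so
# the assembly precomputes one constant rate matrix M covering blood-flow
# transport, permeation, first-order reaction networks, transport
# processes, effect-state relaxation and ledger accumulation. The
# derivative at integration time is M %*% y + u(t) plus the saturable
# reaction terms.

LEDGER_ROUTES <- c("administered", "urine", "feces", "hair", "exhaled",
                   "milk", "other", "transformed")

state_key <- function(chemical, compartment, sub = "") {
  paste(chemical, compartment, sub, sep = "|")
}

resolve_state <- function(layout, chemical, compartment, sub = NULL, what = "reference") {
  rows <- which(layout$chemical == chemical & layout$compartment == compartment)
  if (!length(rows))
    stop(sprintf("unresolved %s: chemical '%s' has no state in compartment '%s'",
                 what, chemical, compartment))
  if (!is.null(sub) && nzchar(sub)) {
    rows <- rows[layout$sub[rows] == sub]
    if (!length(rows))
      stop(sprintf("unresolved %s: no sub-state '%s' for '%s' in '%s'",
                   what, sub, chemical, compartment))
    return(rows[1L])
  }
  if (length(rows) == 1L) return(rows)
  # diffusion-limited tissue referenced without a sub-state: default to the
  # cellular space (where metabolism and storage live)
  cc <- rows[layout$sub[rows] == "C"]
  if (length(cc)) return(cc[1L])
  rows[1L]
}

split_state_ref <- function(ref) {
  ref <- as.character(ref)
  list(compartment = ref[1L], sub = if (length(ref) > 1L) ref[2L] else "")
}

#' Assemble the multi-chemical ODE system
#'
#' Builds the matrix mass-balance system over a body physiology for a set
#' of chemical species: blood-flow transport into perfusion- and
#' diffusion-limited tissues, first-order reaction networks, saturable
#' (Michaelis-Menten) reactions with competitive/noncompetitive inhibition
#' and induction, explicit transport processes (excretion, absorption,
#' inter-compartmental transfer, gas exchange), exposure inputs, and the
#' mixture-interaction layer. Mass-ledger states (administered, excreted
#' by route, net transformed) are appended per chemical so that
#' conservation is auditable.
#'
#' @param body A `body_physiology`.
#' @param chemicals List of [chemical_species()].
#' @param reactions List with elements `gamma` (list of pathways
#'   `list(tissue=, parent=, product=, k=)`, first-order, 1/h) and `mm`
#'   (list of [mm_reaction()]).
#' @param transports List of [transport_process()].
#' @param exposures List of [exposure_profile()].
#' @param interactions List of [interaction_spec()].
#' @param volume_fns Named list (state key -> `function(t)`) of
#'   time-varying volumes used for concentration reporting (e.g. a growing
#'   fetal compartment).
#' @return A `pbtk_system` object with the state layout, the constant rate
#'   matrix, resolved saturable reactions, the input schedule and the
#'   assembly blueprint (so interactions can be re-registered).
#' @export
assemble_system <- function(body, chemicals, reactions = list(),
                            transports = list(), exposures = list(),
                            interactions = list(), volume_fns = list()) {
  validate_body(body)
  chem_names <- vapply(chemicals, `[[`, character(1), "name")
  if (anyDuplicated(chem_names)) stop("duplicate chemical names")
  body_names <- vapply(body$compartments, `[[`, character(1), "name")

  # ---- state layout -------------------------------------------------------
  rows <- list()
  add_row <- function(chemical, compartment, sub, scheme, volume, Q = 0, P = 1, H = 0,
                      convention = "cellular_partitioned") {
    rows[[length(rows) + 1L]] <<- data.frame(
      chemical = chemical, compartment = compartment, sub = sub, scheme = scheme,
      volume = volume, Q = Q, P = P, H = H, convention = convention,
      stringsAsFactors = FALSE)
  }
  for (sp in chemicals) {
    for (st in sp$states) {
      sch <- if (is.null(st$scheme)) "perfusion" else st$scheme
      comp <- st$compartment
      in_body <- comp %in% body_names
      cp <- if (in_body) get_compartment(body, comp) else NULL
      conv <- if (is.null(st$convention)) "cellular_partitioned" else st$convention
      if (sch == "blood") {
        if (!in_body) stop(sprintf("chemical '%s': blood state '%s' not in body", sp$name, comp))
        add_row(sp$name, comp, "", "blood", if (is.null(st$volume)) cp$volume else st$volume)
      } else if (sch == "perfusion") {
        if (!in_body) stop(sprintf("chemical '%s': perfused compartment '%s' not in body", sp$name, comp))
        if (cp$scheme == "storage")
          stop(sprintf("chemical '%s': cannot perfuse storage compartment '%s'", sp$name, comp))
        add_row(sp$name, comp, "", "perfusion", cp$volume, Q = cp$blood_flow, P = st$P)
      } else if (sch == "diffusion") {
        if (!in_body) stop(sprintf("chemical '%s': diffusion compartment '%s' not in body", sp$name, comp))
        if (!is.null(cp$subvolumes)) {
          vE <- cp$subvolumes[["extracellular"]]; vC <- cp$subvolumes[["cellular"]]
        } else if (!is.null(st$f_extracellular)) {
          vE <- cp$volume * st$f_extracellular; vC <- cp$volume - vE
        } else {
          stop(sprintf("chemical '%s': diffusion tissue '%s' needs body subvolumes or f_extracellular",
                       sp$name, comp))
        }
        add_row(sp$name, comp, "E", "diffusion_E", vE, Q = cp$blood_flow, P = st$P, H = st$H, convention = conv)
        add_row(sp$name, comp, "C", "diffusion_C", vC, Q = cp$blood_flow, P = st$P, H = st$H, convention = conv)
      } else if (sch == "pool") {
        vol <- if (!is.null(st$volume)) st$volume else if (in_body) cp$volume else
          stop(sprintf("chemical '%s': pool state '%s' needs a volume", sp$name, comp))
        add_row(sp$name, comp, "", "pool", vol)
      }
    }
  }
  layout <- do.call(rbind, rows)
  layout$key <- state_key(layout$chemical, layout$compartment, layout$sub)
  if (anyDuplicated(layout$key))
    stop("duplicate states: ", paste(layout$key[duplicated(layout$key)], collapse = ", "))
  layout$index <- seq_len(nrow(layout))
  n_amt <- nrow(layout)

  # every circulating species needs exactly one blood hub
  for (sp in chemicals) {
    srows <- layout[layout$chemical == sp$name, ]
    if (any(srows$scheme %in% c("perfusion", "diffusion_E")) &&
        sum(srows$scheme == "blood") != 1L)
      stop(sprintf("chemical '%s': perfused states require exactly one blood state", sp$name))
  }

  # ---- effect states (mixture interaction layer) --------------------------
  mod_specs <- Filter(function(s) s$kind == "metal_vmax_modulation", interactions)
  n_eff <- length(mod_specs)
  eff_index <- if (n_eff) n_amt + seq_len(n_eff) else integer()
  names(eff_index) <- vapply(mod_specs, function(s) s$name, character(1))

  # ---- ledger states ------------------------------------------------------
  n_chem <- length(chem_names)
  ledger_index <- matrix(n_amt + n_eff + seq_len(n_chem * length(LEDGER_ROUTES)),
                         nrow = n_chem, byrow = TRUE,
                         dimnames = list(chem_names, LEDGER_ROUTES))
  n_total <- n_amt + n_eff + n_chem * length(LEDGER_ROUTES)

  M <- matrix(0, n_total, n_total)

  # ---- circulation: blood-flow coupling of perfused tissues ----------------
  for (sp in chemicals) {
    srows <- layout[layout$chemical == sp$name, ]
    bl <- srows$index[srows$scheme == "blood"]
    if (!length(bl)) next
    Vb <- layout$volume[bl]
    for (i in srows$index) {
      sch <- layout$scheme[i]
      if (sch == "perfusion") {
        Q <- layout$Q[i]; V <- layout$volume[i]; P <- layout$P[i]
        M[i, bl] <- M[i, bl] + Q / Vb          # arterial inflow
        M[i, i] <- M[i, i] - Q / (V * P)       # venous outflow at C/P
        M[bl, i] <- M[bl, i] + Q / (V * P)
        M[bl, bl] <- M[bl, bl] - Q / Vb
      } else if (sch == "diffusion_E") {
        Q <- layout$Q[i]; VE <- layout$volume[i]
        ci <- resolve_state(layout, sp$name, layout$compartment[i], "C")
        VC <- layout$volume[ci]; P <- layout$P[i]; H <- layout$H[i]
        M[i, bl] <- M[i, bl] + Q / Vb
        M[i, i] <- M[i, i] - Q / VE            # outlet at extracellular conc
        M[bl, i] <- M[bl, i] + Q / VE
        M[bl, bl] <- M[bl, bl] - Q / Vb
        if (layout$convention[i] == "cellular_partitioned") {
          # permeation H * (C_E - C_C / P)
          M[i, i] <- M[i, i] - H / VE
          M[i, ci] <- M[i, ci] + H / (VC * P)
          M[ci, i] <- M[ci, i] + H / VE
          M[ci, ci] <- M[ci, ci] - H / (VC * P)
        } else {
          # permeation H * (C_E / P - C_C)
          M[i, i] <- M[i, i] - H / (VE * P)
          M[i, ci] <- M[i, ci] + H / VC
          M[ci, i] <- M[ci, i] + H / (VE * P)
          M[ci, ci] <- M[ci, ci] - H / VC
        }
      }
    }
  }

  # ---- first-order reaction networks --------------------------------------
  gam <- reactions$gamma
  if (!is.null(gam)) {
    for (pw in gam) {
      if (!pw$parent %in% chem_names)
        stop(sprintf("reaction parent '%s' is not a declared chemical species", pw$parent))
      tracked <- !is.null(pw$product) && !is.na(pw$product)
      if (tracked && !pw$product %in% chem_names)
        stop(sprintf("reaction product '%s' is not a declared chemical species", pw$product))
      if (pw$k < 0) stop("reaction rate constants must be >= 0")
      pa <- resolve_state(layout, pw$parent, pw$tissue, pw$sub, what = "reaction parent")
      M[pa, pa] <- M[pa, pa] - pw$k
      M[ledger_index[pw$parent, "transformed"], pa] <-
        M[ledger_index[pw$parent, "transformed"], pa] + pw$k
      if (tracked) {
        pr <- resolve_state(layout, pw$product, pw$tissue, pw$sub, what = "reaction product")
        M[pr, pa] <- M[pr, pa] + pw$k
        M[ledger_index[pw$product, "transformed"], pa] <-
          M[ledger_index[pw$product, "transformed"], pa] - pw$k
      }
    }
  }

  # ---- transport processes ------------------------------------------------
  for (tp in transports) {
    if (!tp$chemical %in% chem_names)
      stop(sprintf("transport references unknown chemical '%s'", tp$chemical))
    srcref <- split_state_ref(tp$source)
    si <- resolve_state(layout, tp$chemical, srcref$compartment, srcref$sub, what = "transport source")
    k <- if (!is.null(tp$rate)) tp$rate else tp$clearance / layout$volume[si]
    M[si, si] <- M[si, si] - k
    if (!is.null(tp$route)) {
      M[ledger_index[tp$chemical, tp$route], si] <-
        M[ledger_index[tp$chemical, tp$route], si] + k
    } else {
      if (is.null(tp$destination))
        stop(sprintf("transport '%s' of '%s' needs a destination", tp$kind, tp$chemical))
      dstref <- split_state_ref(tp$destination)
      di <- resolve_state(layout, tp$chemical, dstref$compartment, dstref$sub, what = "transport destination")
      M[di, si] <- M[di, si] + k
    }
  }

  # ---- saturable (Michaelis-Menten) reactions ------------------------------
  mm_list <- reactions$mm
  if (is.null(mm_list)) mm_list <- list()
  # competitive / noncompetitive / induction interaction specs attach to reactions
  for (spec in interactions) {
    if (spec$kind == "competitive") {
      hit <- FALSE
      for (j in seq_along(mm_list)) {
        if (mm_list[[j]]$name %in% spec$targets) {
          mm_list[[j]]$competitive[spec$chemical] <- spec$I
          hit <- TRUE
        }
      }
      if (!hit) stop(sprintf("interaction '%s': no target reaction found", spec$name))
    } else if (spec$kind %in% c("noncompetitive", "induction")) {
      hit <- FALSE
      for (j in seq_along(mm_list)) {
        if (mm_list[[j]]$name %in% spec$targets) {
          mod <- if (spec$kind == "noncompetitive")
            list(kind = "noncompetitive", chemical = spec$chemical,
                 compartment = spec$compartment, K = spec$K_nc)
          else list(kind = "induction", factor = spec$factor)
          mm_list[[j]]$modifiers <- c(mm_list[[j]]$modifiers, list(mod))
          hit <- TRUE
        }
      }
      if (!hit) stop(sprintf("interaction '%s': no target reaction found", spec$name))
    }
  }
  mm_resolved <- lapply(mm_list, function(r) {
    if (!r$substrate %in% chem_names)
      stop(sprintf("reaction substrate '%s' is not a declared chemical species", r$substrate))
    tracked <- !is.null(r$product) && !is.na(r$product)
    if (tracked && !r$product %in% chem_names)
      stop(sprintf("reaction product '%s' is not a declared chemical species", r$product))
    si <- resolve_state(layout, r$substrate, r$tissue, what = "reaction substrate")
    out <- list(name = r$name, sub = si, Vsub = layout$volume[si],
                prod = NA_integer_, Km = r$K_m, Vmax = r$V_max,
                led_sub = ledger_index[r$substrate, "transformed"],
                led_prod = NA_integer_)
    if (tracked) {
      pi <- resolve_state(layout, r$product, r$tissue, what = "reaction product")
      out$prod <- pi
      out$led_prod <- ledger_index[r$product, "transformed"]
    }
    if (length(r$competitive)) {
      out$inh_idx <- vapply(names(r$competitive), function(k)
        resolve_state(layout, k, r$tissue, what = "competitive inhibitor"), integer(1))
      out$inh_V <- layout$volume[out$inh_idx]
      out$inh_I <- as.numeric(r$competitive)
    } else {
      out$inh_idx <- integer()
    }
    out$mods <- lapply(r$modifiers, function(m) {
      if (m$kind == "noncompetitive") {
        idx <- resolve_state(layout, m$chemical, m$compartment, what = "noncompetitive modifier")
        list(kind = "noncompetitive", idx = idx, V = layout$volume[idx], K = m$K)
      } else if (m$kind == "induction") {
        list(kind = "induction", factor = m$factor)
      } else stop(sprintf("unknown structural modifier kind '%s'", m$kind))
    })
    out
  })

  # ---- interaction effect states ------------------------------------------
  for (j in seq_along(mod_specs)) {
    spec <- mod_specs[[j]]
    e <- eff_index[[j]]
    if (spec$tau <= 0) stop("interaction lag time-constant tau must be > 0")
    for (src in spec$sources) {
      if (src$weight < 0) stop("interaction weights must be >= 0")
      si <- resolve_state(layout, src$chemical, src$compartment, what = "interaction source")
      M[e, si] <- M[e, si] + src$weight / (layout$volume[si] * spec$tau)
    }
    M[e, e] <- M[e, e] - 1 / spec$tau
    hit <- FALSE
    for (q in seq_along(mm_resolved)) {
      if (mm_resolved[[q]]$name %in% spec$targets) {
        mm_resolved[[q]]$mods <- c(mm_resolved[[q]]$mods,
                                   list(list(kind = "interaction", eff = e)))
        hit <- TRUE
      }
    }
    if (!hit) stop(sprintf("interaction '%s': no target reaction found", spec$name))
  }

  # ---- exposure inputs -----------------------------------------------------
  exp_resolved <- lapply(exposures, function(p) {
    if (!p$chemical %in% chem_names)
      stop(sprintf("exposure references unknown chemical '%s'", p$chemical))
    tref <- split_state_ref(p$target)
    ti <- resolve_state(layout, p$chemical, tref$compartment, tref$sub, what = "exposure target")
    list(profile = p, target = ti,
         led_adm = ledger_index[p$chemical, "administered"],
         led_fec = ledger_index[p$chemical, "feces"])
  })
  breakpoints <- sort(unique(unlist(lapply(exposures, profile_breakpoints))))

  structure(list(
    body = body, chemicals = chemicals, layout = layout,
    n_amt = n_amt, n_eff = n_eff, n_total = n_total,
    eff_index = eff_index, ledger_index = ledger_index,
    M = M, mm = mm_resolved, exposures = exp_resolved,
    breakpoints = breakpoints, volume_fns = volume_fns,
    blueprint = list(body = body, chemicals = chemicals, reactions = reactions,
                     transports = transports, exposures = exposures,
                     interactions = interactions, volume_fns = volume_fns)
  ), class = "pbtk_system")
}

#' @export
print.pbtk_system <- function(x, ...) {
  cat(sprintf("pbtk_system: %d chemicals, %d amount states, %d effect states, %d saturable reactions\n",
              length(x$chemicals), x$n_amt, x$n_eff, length(x$mm)))
  invisible(x)
}

# piecewise-constant input vector at time t (full state length)
input_vector <- function(system, t) {
  u <- numeric(system$n_total)
  for (ex in system$exposures) {
    p <- ex$profile
    if (p$route == "oral_bolus") next
    s <- profile_scale(p, t)
    for (ev in p$events) {
      if (t < ev$start || t >= ev$end) next
      if (p$route == "inhalation") {
        rate <- p$alveolar_ventilation * ev$magnitude * s
        u[ex$target] <- u[ex$target] + rate
        u[ex$led_adm] <- u[ex$led_adm] + rate
      } else {
        rate <- ev$magnitude * s
        u[ex$target] <- u[ex$target] + p$F_abs * rate
        u[ex$led_adm] <- u[ex$led_adm] + rate
        u[ex$led_fec] <- u[ex$led_fec] + (1 - p$F_abs) * rate
      }
    }
  }
  u
}

# bolus state jumps scheduled at time t; returns an additive state delta
bolus_delta <- function(system, t) {
  d <- numeric(system$n_total)
  any_hit <- FALSE
  for (ex in system$exposures) {
    p <- ex$profile
    if (p$route != "oral_bolus") next
    for (ev in p$events) {
      if (abs(ev$time - t) < 1e-9) {
        s <- profile_scale(p, ev$time)
        d[ex$target] <- d[ex$target] + p$F_abs * ev$amount * s
        d[ex$led_adm] <- d[ex$led_adm] + ev$amount * s
        d[ex$led_fec] <- d[ex$led_fec] + (1 - p$F_abs) * ev$amount * s
        any_hit <- TRUE
      }
    }
  }
  if (any_hit) d else NULL
}
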