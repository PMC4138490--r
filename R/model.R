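# Model assembly: configuration -> engine-ready structure.

MECH_ORDER <- c("leak", "trp", "h", "na", "kv", "ka", "kca", "kslow",
                "cahva", "calva")
MECH_KIND <- c(leak = 0L, trp = 1L, h = 2L, na = 3L, kv = 4L, ka = 5L,
               kca = 6L, kslow = 7L, cahva = 8L, calva = 9L)

.ubc_env <- new.env(parent = emptyenv())

#' Canonical model configuration
#'
#' Reads (and caches) the packaged canonical configuration, a YAML file
#' holding the morphology, the maximum-conductance table with reversal
#' potentials, per-compartment density multipliers, calcium-shell and
#' cascade parameters.
#'
#' @param path optional path to an alternative configuration file.
#' @return nested configuration list.
#' @export
ubc_config <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.ubc_env$config)) return(.ubc_env$config)
    path <- system.file("extdata", "ubc-canonical.yaml", package = "ubcsim",
                        mustWork = TRUE)
    cfg <- read_model_config(path)
    .ubc_env$config <- cfg
    return(cfg)
  }
  read_model_config(path)
}

#' Read / write a model configuration
#'
#' Configurations round-trip through YAML without loss of precision
#' (numbers are serialised with full precision).
#'
#' @param path file path.
#' @return configuration list.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  cfg
}

#' @rdname read_model_config
#' @param cfg configuration list.
#' @export
write_model_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}

validate_config <- function(cfg) {
  need <- c("temperature_c", "morphology", "mechanisms", "calcium", "cascade")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("config is missing fields: ", paste(miss, collapse = ", "))
  miss_m <- setdiff(MECH_ORDER, names(cfg$mechanisms))
  if (length(miss_m)) stop("config is missing mechanisms: ",
                           paste(miss_m, collapse = ", "))
  for (m in MECH_ORDER) {
    mm <- cfg$mechanisms[[m]]
    gkey <- if (m == "calva") "perm" else "gmax"
    if (is.null(mm[[gkey]]) || mm[[gkey]] < 0)
      stop("mechanism ", m, ": missing or negative ", gkey)
  }
  invisible(cfg)
}

# compartment group of each of the 13 compartments
compartment_groups <- function(morph) {
  vapply(morph$compartments, function(cp) {
    nm <- cp$name
    if (grepl("^ais", nm)) "ais" else if (grepl("^axon", nm)) "axon" else nm
  }, character(1))
}

#' Assemble a runnable UBC model
#'
#' Builds the engine-ready model from a configuration: morphology with
#' absolute capacitances and axial couplings, absolute conductances per
#' mechanism and compartment (density multiplier x maximum density x
#' area), temperature-corrected rate multipliers, calcium shells and
#' cascade parameters.
#'
#' @param config a configuration list (default: packaged canonical).
#' @return a `ubc_model` object.
#' @export
ubc_model <- function(config = ubc_config()) {
  morph <- build_canonical_ubc(config$morphology)
  n <- length(morph$compartments)
  groups <- compartment_groups(morph)
  areas_um2 <- vapply(morph$compartments, membrane_area, numeric(1))
  areas_cm2 <- areas_um2 * 1e-8
  # cm2 * uF/cm2 = uF = 1e3 nF
  cap_nF <- areas_cm2 * vapply(morph$compartments, `[[`, numeric(1),
                               "cm_uF_cm2") * 1e3
  gax <- numeric(n)
  for (i in seq_len(n)) {
    p <- morph$parent[i]
    gax[i] <- if (p == 0L) 0 else
      axial_conductance(morph$compartments[[i]], morph$compartments[[p]])
  }
  tsim <- config$temperature_c

  mechs <- vector("list", length(MECH_ORDER))
  names(mechs) <- MECH_ORDER
  for (m in MECH_ORDER) {
    mm <- config$mechanisms[[m]]
    mult <- numeric(n)
    for (g in names(mm$density)) mult[groups == g] <- mm$density[[g]]
    base <- if (m == "calva") mm$perm else mm$gmax
    g_abs <- if (m == "calva") {
      base * mult * areas_cm2            # cm/s * cm2 = cm3/s
    } else {
      base * mult * areas_cm2 * 1e6      # S -> uS
    }
    q <- q10_factor(mm$q10 %||% 3, tsim, mm$t_exp %||% tsim)
    e <- if (m %in% c("cahva", "calva")) config$calcium$e_ca_init_mV else mm$erev
    entry <- list(name = m, kind = MECH_KIND[[m]], g_abs = g_abs,
                  erev = e, q = q)
    if (m == "calva")
      # inactivation carries its own Q10 and an optional tau scale
      # (folded into the rate multiplier: rates = q / tauh_scale)
      entry$q2 <- q10_factor(mm$q10_inact %||% 3, tsim, mm$t_exp %||% tsim) /
        (mm$tauh_scale %||% 1)
    if (m == "trp") entry$baseline <- mm$baseline
    if (m == "h") {
      entry <- c(entry, mm[c("vhalf", "slope", "tau_a", "tau_ka", "tau_b",
                             "tau_kb", "tau_scale")])
      entry$tau_mode <- if (identical(mm$tau_mode, "printed")) 1L else 0L
    }
    if (m == "kv") entry[c("taum_scale", "tauh_scale")] <-
        mm[c("taum_scale", "tauh_scale")]
    if (m == "na") entry$markov <- utils::modifyList(na_markov_params(),
                                                     mm$markov %||% list())
    mechs[[m]] <- entry
  }

  cal <- config$calcium
  has_shell <- groups %in% cal$shells
  depth_cm <- cal$depth_nm * 1e-7
  vol <- areas_cm2 * depth_cm
  kflux <- ifelse(has_shell, 1e-6 / (2 * 96485.332 * vol), 0)
  cao <- ca_out_for_reversal(cal$e_ca_init_mV, cal$ca_rest_mM, tsim)

  casc <- config$cascade

  engine <- list(
    n_comp = n,
    cap = cap_nF,
    parent = as.integer(morph$parent - 1L),
    g_axial = gax,
    temperature = tsim,
    mechs = unname(mechs),
    ca = list(has_shell = has_shell, kflux = kflux, beta = cal$beta_ca,
              ca0 = cal$ca_rest_mM, cao = cao),
    cascade = casc
  )
  structure(list(config = config, morphology = morph, groups = groups,
                 areas_um2 = areas_um2, engine = engine,
                 blocked = character(0)),
            class = "ubc_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Zero out mechanisms (simulated pharmacology)
#'
#' Returns a copy of the model with the maximum conductance (or GHK
#' permeability) of the listed mechanisms set to zero; the original model
#' is untouched.
#'
#' @param model a [ubc_model()].
#' @param mechanisms character vector of mechanism names
#'   (`"h"`, `"trp"`, `"na"`, `"kv"`, `"ka"`, `"kca"`, `"kslow"`,
#'   `"cahva"`, `"calva"`, `"leak"`).
#' @return a modified copy of the model.
#' @export
apply_channel_block <- function(model, mechanisms) {
  if (length(mechanisms) == 0) return(model)
  bad <- setdiff(mechanisms, MECH_ORDER)
  if (length(bad)) stop("unknown mechanism(s): ", paste(bad, collapse = ", "))
  for (m in mechanisms) {
    i <- match(m, MECH_ORDER)
    model$engine$mechs[[i]]$g_abs[] <- 0
  }
  model$blocked <- union(model$blocked, mechanisms)
  model
}

#' Scale a mechanism's maximum conductance
#'
#' Used by the robustness sweep: multiplies the absolute conductance of
#' one mechanism (all compartments) by `factor`.
#'
#' @param model a [ubc_model()].
#' @param mechanism mechanism name.
#' @param factor non-negative scale factor.
#' @return a modified copy of the model.
#' @export
scale_gmax <- function(model, mechanism, factor) {
  stopifnot(factor >= 0, length(mechanism) == 1)
  i <- match(mechanism, MECH_ORDER)
  if (is.na(i)) stop("unknown mechanism: ", mechanism)
  model$engine$mechs[[i]]$g_abs <- model$engine$mechs[[i]]$g_abs * factor
  model
}

#' @export
print.ubc_model <- function(x, ...) {
  cat("UBC model:", x$engine$n_comp, "compartments,",
      sprintf("%.2f pF total capacitance", sum(x$engine$cap) * 1e3), "\n")
  if (length(x$blocked)) cat("blocked mechanisms:",
                             paste(x$blocked, collapse = ", "), "\n")
  invisible(x)
}

#' Stable configuration hash
#'
#' Hash of the deparsed configuration, recorded in trace outputs so that
#' any two runs with identical configuration are identifiable.
#'
#' @param config configuration list.
#' @return character scalar.
#' @export
config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "\n")
  # polynomial rolling hash over two different moduli (identity check only)
  h1 <- 0; h2 <- 0
  for (b in utf8ToInt(txt)) {
    h1 <- (h1 * 131 + b) %% 2147483647
    h2 <- (h2 * 137 + b) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}
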