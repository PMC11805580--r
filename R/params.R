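# Model parameters: literature defaults, validation, YAML (de)serialization.
#
# All internal quantities are SI (m, s, Pa) except concentrations, which are
# kept in micromolar throughout.  Exposure-type outputs are reported in uM*h;
# the seconds-to-hours conversion lives in the single constant below.

#' @keywords internal
SEC_PER_HOUR <- 3600

MMHG_TO_PA <- 133.322

#' Default model parameters
#'
#' Returns the full parameter set of the tumor-cord electro-chemotherapy
#' model: electrical properties of tissue and vessel wall, transport and
#' reaction constants for doxorubicin, cord geometry, the vasoconstriction
#' law, the electroporation protocol, blood characteristics, the inlet
#' pharmacokinetic profile and the numerical controls.  Values are the
#' literature defaults for a doxorubicin tumor-cord simulation; every field
#' can be overridden through [cord_params()] or a YAML file via
#' [load_config()].
#'
#' @return A validated object of class `cord_params` (a named nested list).
#' @seealso [cord_params()], [load_config()], [write_config()]
#' @examples
#' p <- default_params()
#' p$transport$C0     # binding-site concentration, uM
#' p$geometry$rv0     # initial vessel radius, m
#' @export
default_params <- function() {
  p <- list(
    electrical = list(
      tissue = list(
        E_rev = 46e3, E_irrev = 70e3,
        alpha_star = 10, beta_star = 8,
        sigma_max = 3.141e-1, sigma_min = 1.998e-2,
        tau_i = 100
      ),
      vessel_wall = list(
        E_rev = 46e3, E_irrev = 175e3,
        alpha_star = 10, beta_star = 8,
        sigma_max = 6.250e-1, sigma_min = 0.630e-2,
        tau_i = 100
      )
    ),
    transport = list(
      C0 = 2.6e3,           # binding-site concentration, uM
      k1_min = 1.0e-9,      # cell-membrane permeability floor, m/s
      k1_max = 1.0e-6,      # fully permeabilized membrane, m/s
      k2 = 0.9e-6,          # association rate, uM^-1 s^-1
      k_minus2 = 14e-6,     # dissociation rate, s^-1
      kv_min = 2.8e-6,      # vessel-wall diffusive permeability, m/s
      kv_max = 4.4e-6,
      kvc_min = 2.7e-12,    # vessel-wall hydraulic permeability, m/(Pa s)
      kvc_max = 2.1e-11,
      D0 = 5.0e-11,         # interstitial diffusivity, m^2/s
      k_o = 2.5e-6,         # retained as metadata; unused by the model
      Mw_dox = 543.52       # g/mol, metadata
    ),
    geometry = list(
      rv0 = 16e-6,          # initial vessel radius, m
      R_cord = 200e-6,      # cord outer radius, m
      L_cord = 400e-6,      # cord length, m
      delta1_0 = 5.88e-2,   # extracellular volume fraction
      delta2_0 = 9.41e-1,   # intracellular volume fraction
      alpha0 = 1.94028e5    # membrane area density, 1/m
    ),
    vaso = list(
      tau_r = 330,          # vasoconstriction decay time, s
      m_r = 6.49e-5,        # field coefficient, (V/m)^-1
      rhat_min = 0.25       # minimum normalized vessel radius
    ),
    protocol = list(
      E = 0,                          # applied field, V/m
      N_ep = 6,                       # electroporation sessions
      session_times = seq(0, 20, by = 4) * SEC_PER_HOUR,
      d_pulses = 10,                  # s, pulse spacing (metadata)
      T_ep = 600,                     # s, session duration (metadata)
      N_pulses = 5,                   # per session (metadata)
      t_pulse = 1e-4,                 # s (metadata)
      f_pulse = 1,                    # Hz (metadata)
      T_chemo = 24 * SEC_PER_HOUR     # total simulated time, s
    ),
    blood = list(
      lambda_inl = 1e-4,    # inlet blood velocity, m/s
      p_inl = 150 * MMHG_TO_PA,  # inlet pressure, Pa (150 mmHg)
      p_p = 0,              # permeate pressure, Pa
      mu = 1.24e-3          # plasma viscosity, Pa s (1.24 cP)
    ),
    pk = list(
      kind = "TPK",
      TPK = list(
        D_dose = 1.1983e2,  # umol
        tau_prime = 180,    # s, infusion duration
        Aprime = 7.46e-2, Adprime = 2.69e-3,   # 1/l, 1/s
        Bprime = 2.49e-3, Bdprime = 2.83e-4,
        Cprime = 5.52e-4, Cdprime = 1.18e-5
      ),
      MPK = list(
        Aprime = 50,        # uM
        Adprime = 0.005     # 1/s
      )
    ),
    numerics = list(
      n_r = 31, n_z = 13,
      dt = 5,               # s
      omega = 0.8,          # under-relaxation factor
      S_L = 1, S_T = 1, S_C = 1,   # conditioning scale factors
      gs_tol = 1e-6,        # Gauss-Seidel relative error threshold
      max_outer = 200,
      remesh_threshold = 0.9,
      remesh_mode = "literal",     # or "delta"
      tie_tol = 1e-9,       # relative tolerance for "unchanged"
      eps_div = 1e-12,      # uM, denominators below this flag a ratio undefined
      kvc_interpolate = TRUE,      # electro-modulate hydraulic permeability
      vaso_active = TRUE,          # apply vasoconstriction law when E > 0
      report_times = c(0, 0.5, 1, 2, 3, 6, 9, 12, 15, 18, 21, 24) * SEC_PER_HOUR
    )
  )
  p$blood$Q_inl <- p$blood$lambda_inl * pi * p$geometry$rv0^2
  structure(p, class = "cord_params")
}

#' Construct a parameter set with overrides
#'
#' Starts from [default_params()] and deep-merges any overrides given either
#' as a nested list or as `section.field` dotted names.
#'
#' @param ... Named overrides.  Either top-level sections as nested lists
#'   (`protocol = list(E = 46e3)`) or dotted scalar names
#'   (`protocol.E = 46e3`, `pk.kind = "MPK"`).
#' @param base Parameter set to start from (default [default_params()]).
#' @return A validated `cord_params` object.
#' @examples
#' p <- cord_params(protocol.E = 46e3, blood.lambda_inl = 1e-3, pk.kind = "MPK")
#' p$protocol$E
#' @export
cord_params <- function(..., base = default_params()) {
  dots <- list(...)
  p <- unclass(base)
  for (nm in names(dots)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1L) {
      if (is.list(dots[[nm]])) {
        p[[nm]] <- utils::modifyList(p[[nm]] %||% list(), dots[[nm]])
      } else {
        p[[nm]] <- dots[[nm]]
      }
    } else {
      p[[parts]] <- dots[[nm]]
    }
  }
  p <- derive_params(p)
  validate_params(structure(p, class = "cord_params"))
}

derive_params <- function(p) {
  p$blood$Q_inl <- p$blood$lambda_inl * pi * p$geometry$rv0^2
  # sessions scheduled past the simulated horizon can never fire; drop them
  # so a shortened horizon keeps a consistent protocol
  st <- p$protocol$session_times
  p$protocol$session_times <- st[st <= p$protocol$T_chemo]
  p$protocol$N_ep <- length(p$protocol$session_times)
  p
}

check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    stop("invalid parameter `", field, "`: ", msg, call. = FALSE)
  }
}

#' Validate a parameter set
#'
#' Checks positivity, ordering and range constraints on every parameter
#' group and fails with an error naming the offending field.
#'
#' @param p A `cord_params` object (or plain nested list with the same shape).
#' @return `p`, invisibly classed as `cord_params`, if valid.
#' @export
validate_params <- function(p) {
  for (side in c("tissue", "vessel_wall")) {
    e <- p$electrical[[side]]
    check_that(e$E_rev < e$E_irrev, paste0("electrical.", side, ".E_rev"),
               "reversible threshold must be below the irreversible one")
    check_that(e$sigma_min < e$sigma_max, paste0("electrical.", side, ".sigma_min"),
               "sigma_min must be below sigma_max")
    check_that(e$tau_i > 0, paste0("electrical.", side, ".tau_i"), "must be > 0")
  }
  tr <- p$transport
  for (f in c("C0", "k1_min", "k1_max", "k2", "k_minus2", "kv_min", "kv_max",
              "kvc_min", "kvc_max", "D0")) {
    check_that(is.numeric(tr[[f]]) && tr[[f]] > 0, paste0("transport.", f),
               "must be strictly positive")
  }
  check_that(tr$k1_min <= tr$k1_max, "transport.k1_min", "k1_min must be <= k1_max")
  check_that(tr$kv_min <= tr$kv_max, "transport.kv_min", "kv_min must be <= kv_max")
  check_that(tr$kvc_min <= tr$kvc_max, "transport.kvc_min",
             "kvc_min must be <= kvc_max")
  g <- p$geometry
  check_that(g$rv0 > 0 && g$rv0 < g$R_cord, "geometry.rv0",
             "must satisfy 0 < rv0 < R_cord")
  check_that(g$L_cord > 0, "geometry.L_cord", "must be > 0")
  check_that(g$delta1_0 > 0 && g$delta2_0 > 0, "geometry.delta1_0",
             "volume fractions must be positive")
  check_that(g$delta1_0 + g$delta2_0 <= 1, "geometry.delta2_0",
             "volume fractions must sum to at most 1")
  check_that(g$alpha0 > 0, "geometry.alpha0", "must be > 0")
  v <- p$vaso
  check_that(v$rhat_min > 0 && v$rhat_min < 1, "vaso.rhat_min",
             "must lie in (0, 1)")
  check_that(v$tau_r > 0, "vaso.tau_r", "must be > 0")
  pr <- p$protocol
  check_that(is.numeric(pr$E) && length(pr$E) == 1L && pr$E >= 0, "protocol.E",
             "field magnitude must be a single value >= 0")
  check_that(pr$T_chemo > 0, "protocol.T_chemo", "must be > 0")
  st <- pr$session_times
  check_that(length(st) == 0L || (!is.unsorted(st) && all(st >= 0) &&
             all(st <= pr$T_chemo)), "protocol.session_times",
             "must be sorted and within [0, T_chemo]")
  check_that(pr$N_ep == length(st), "protocol.N_ep",
             "must equal the number of session times")
  b <- p$blood
  check_that(b$lambda_inl > 0, "blood.lambda_inl", "must be > 0")
  check_that(b$mu > 0, "blood.mu", "must be > 0")
  check_that(b$p_inl >= b$p_p, "blood.p_inl", "inlet pressure must be >= permeate")
  check_that(p$pk$kind %in% c("TPK", "MPK"), "pk.kind", "must be 'TPK' or 'MPK'")
  if (p$pk$kind == "TPK") {
    tpk <- p$pk$TPK
    check_that(tpk$tau_prime > 0, "pk.TPK.tau_prime", "must be > 0")
    for (f in c("Adprime", "Bdprime", "Cdprime")) {
      check_that(tpk[[f]] > 0, paste0("pk.TPK.", f), "rate must be strictly positive")
    }
  } else {
    check_that(p$pk$MPK$Adprime > 0, "pk.MPK.Adprime", "rate must be strictly positive")
  }
  n <- p$numerics
  check_that(n$dt > 0, "numerics.dt", "must be > 0")
  check_that(n$gs_tol > 0, "numerics.gs_tol", "must be > 0")
  check_that(n$omega > 0 && n$omega <= 1, "numerics.omega", "must lie in (0, 1]")
  check_that(n$n_r >= 3 && n$n_z >= 2, "numerics.n_r", "grid must be at least 3 x 2")
  check_that(n$remesh_mode %in% c("literal", "delta"), "numerics.remesh_mode",
             "must be 'literal' or 'delta'")
  invisible(structure(p, class = "cord_params"))
}

#' @export
print.cord_params <- function(x, ...) {
  cat("<cord_params>\n")
  cat(sprintf("  E = %g V/m, lambda_inl = %g m/s, PK = %s\n",
              x$protocol$E, x$blood$lambda_inl, x$pk$kind))
  cat(sprintf("  grid %d x %d, dt = %g s, T = %g h, %d EP sessions\n",
              x$numerics$n_r, x$numerics$n_z, x$numerics$dt,
              x$protocol$T_chemo / SEC_PER_HOUR, x$protocol$N_ep))
  invisible(x)
}

deep_merge <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- deep_merge(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Load a run configuration from YAML
#'
#' Reads a YAML key-value document with the same nested layout as
#' [default_params()] and merges it on top of the defaults.  All keys are
#' optional; unspecified fields take their default values.  Pressures may be
#' given either in Pa (`p_inl`) or in mmHg (`p_inl_mmHg`, `p_p_mmHg`), the
#' latter being converted at load (1 mmHg = 133.322 Pa).
#'
#' @param path Path to a YAML file.
#' @return A validated `cord_params` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.null(raw$blood$p_inl_mmHg)) {
    raw$blood$p_inl <- raw$blood$p_inl_mmHg * MMHG_TO_PA
    raw$blood$p_inl_mmHg <- NULL
  }
  if (!is.null(raw$blood$p_p_mmHg)) {
    raw$blood$p_p <- raw$blood$p_p_mmHg * MMHG_TO_PA
    raw$blood$p_p_mmHg <- NULL
  }
  p <- deep_merge(unclass(default_params()), raw)
  p <- derive_params(p)
  validate_params(structure(p, class = "cord_params"))
}

#' Serialize a parameter set to YAML
#'
#' The written file round-trips: `load_config(write_config(p, f))` compares
#' equal to `p`.
#'
#' @param p A `cord_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(p, path) {
  stopifnot(inherits(p, "cord_params"))
  yaml::write_yaml(unclass(p), path, precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
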