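# Configuration: defaults, validation, YAML I/O. Every model parameter lives
# here with its unit embedded in the key name (_per_day, _per_min, _min,
# _days, _um). Values marked [assumed] below are package defaults standing in
# for quantities the model needs but that are not fixed by the printed
# mechanism description; all are overridable.

#' Default simulation configuration
#'
#' Returns the complete nested parameter list for the model. Mechanism
#' constants: the TME starts with 100 tumor cells and no CTLs; the tumor step
#' is 15 min and the immune step 7.5 min; perforin/granzyme killing of HA
#' targets takes 30 min and Fas/FasL killing of LA targets 2 h; ten
#' replicates per parameter set. All remaining rates, concentrations and
#' geometric choices are documented package defaults (see the methods
#' vignette) and can be overridden via [tme_config()] or a YAML file read by
#' [read_config()].
#'
#' @return nested named list of parameters.
#' @seealso [tme_config()], [validate_config()]
#' @export
default_config <- function() {
  list(
    lattice = list(
      dims = c(40L, 40L, 40L),     # sites per axis [assumed]
      site_length_um = 20,         # [assumed]
      regions_per_axis = 5L        # global-method region partition [assumed]
    ),
    time = list(
      dt_tumor_min = 15,           # tumor step
      dt_immune_min = 7.5,         # immune step
      t_end_days = 25              # simulated horizon; Day-25 endpoint
    ),
    init = list(
      n_tumor = 100L,              # initial tumor cells near the center
      frac_mutant = 0.5,           # initial FGFR3-mutant fraction
      frac_ha = 0.5                # initial high-antigen fraction
    ),
    tumor = list(
      alpha_T_per_day = 0.5,       # base proliferation rate [assumed]
      alpha_F_per_day = 1.25,      # max FGFR3 proliferation increment [assumed]
      delta_T_per_day = 0.1,       # base apoptosis rate [assumed]
      eps_F = 0.9,                 # max fractional apoptosis reduction [assumed]
      crowd_threshold = 24L,       # max occupied Moore neighbors for division [assumed]
      sigma_HA = 1.0,              # ISF secretion, HA cells (conc/min) [assumed]
      sigma_LA = 0.1               # ISF secretion, LA cells (conc/min) [assumed]
    ),
    immune = list(
      alpha_I_per_day = 0.4,       # base CTL proliferation [assumed]
      boost_max = 4,               # max ISF proliferation multiplier increment [assumed]
      k_isf = 8,                   # ISF half-saturation (conc) [assumed]
      delta_I_per_day = 0.35,      # CTL apoptosis [assumed]
      m_per_min = 0.05,            # movement event rate [assumed]
      n_move = 4L,                 # lattice steps per movement event [assumed]
      lambda_chemo = 5,            # chemotactic sensitivity (per conc) [assumed]
      beta_per_min = 0.2,          # conjugation attempt rate [assumed]
      T_perforin_min = 30,         # HA kill duration (perforin/granzyme)
      T_fas_min = 120,             # LA kill duration (Fas/FasL)
      d_a_per_day = 0.5,           # AICD rate once idle [assumed]
      tau_idle_min = 1440,         # idle threshold enabling AICD [assumed]
      rho_max_per_day = 24,        # max exhaustion rate [assumed]
      C50 = 0.3,                   # complex conc at half-max exhaustion [assumed]
      hill_h = 2,                  # exhaustion Hill coefficient [assumed]
      r_rec_per_day = 0.25,        # recruited CTLs per tumor cell per day [assumed]
      s_max = 0.9                  # max recruitment suppression fraction [assumed]
    ),
    isf = list(
      diffusion_site2_per_min = 0.3,  # [assumed]
      decay_per_min = 0.05            # [assumed]
    ),
    fgfr3 = list(
      R_total = 1,                 # total FGFR3 per mutant cell (conc units) [assumed]
      k_dim_per_min = 0.1,         # dimerization on-rate (/conc/min) [assumed]
      k_undim_per_min = 0.001,     # dimer dissociation (/min) [assumed]
      k_on_I_per_min = 10,         # SMI-monomer binding (/conc/min) [assumed]
      k_off_I_per_min = 0.01,      # SMI unbinding (/min) [assumed]
      drug_diff_per_min = 0.5,     # SMI inter-region exchange rate [assumed]
      phi_normalization = "half"   # "half": dimers / (R_total/2); "total": / R_total
    ),
    checkpoint = list(
      P_per_cell = 10,             # PD-1 per CTL (conc units x site^3) [assumed]
      L_per_cell = 10,             # PD-L1 per tumor cell [assumed]
      Kd_PL = 1,                   # PD-1:PD-L1 dissociation constant [assumed]
      k_on_A_per_min = 1,          # antibody-PD-1 binding (/conc/min) [assumed]
      k_off_A_per_min = 0.01,      # antibody unbinding (/min) [assumed]
      drug_diff_per_min = 0.5      # antibody inter-region exchange [assumed]
    ),
    pk = list(
      smi = list(
        half_life_min = 360,       # ~6 h elimination half-life [assumed]
        k12_per_min = 0.002, k21_per_min = 0.002,
        k_tme_per_min = 0.005,     # central -> TME transfer [assumed]
        dose_amount = 100,         # amount units per bolus [assumed]
        dose_interval_days = 1     # daily dosing within window [assumed]
      ),
      antibody = list(
        half_life_min = 14400,     # ~10 d elimination half-life [assumed]
        k12_per_min = 5e-04, k21_per_min = 5e-04,
        k_tme_per_min = 0.001,
        dose_amount = 200,
        dose_interval_days = 3     # every 3 days within window [assumed]
      )
    ),
    therapy = list(
      arm = "control",             # one of control, ICI, aFGFR3, FGFR3_first, ICI_first
      mono_start_day = 14, mono_end_day = 21,
      combo_first_start_day = 14, combo_switch_day = 21, combo_end_day = 28
    ),
    measure = list(
      snapshot_days = c(12, 20, 25),
      log_every_steps = 1L
    ),
    run = list(n_reps = 10L)
  )
}

#' Validate (and complete) a configuration
#'
#' Checks a raw configuration list against the schema of [default_config()]:
#' unknown keys are rejected by name, missing keys are filled with defaults,
#' and cross-parameter constraints are enforced (immune step divides tumor
#' step; HA cells secrete more ISF than LA cells; perforin killing is faster
#' than Fas killing; lattice dims divisible by the region partition).
#'
#' @param raw nested list of overrides (possibly partial).
#' @return the completed, validated configuration.
#' @export
validate_config <- function(raw = list()) {
  def <- default_config()
  check_keys(raw, def, path = character(0))
  cfg <- modifyList(def, raw)
  with(cfg, {
    la <- lattice; tm <- time; tu <- tumor; im <- immune
    if (length(la$dims) != 3 || any(la$dims < 3))
      stop("lattice$dims must be three values >= 3")
    if (la$regions_per_axis < 1) stop("lattice$regions_per_axis must be >= 1")
    if (any(as.integer(la$dims) %% as.integer(la$regions_per_axis) != 0))
      stop("lattice$dims must be divisible by lattice$regions_per_axis")
    r <- tm$dt_tumor_min / tm$dt_immune_min
    if (tm$dt_tumor_min <= 0 || tm$dt_immune_min <= 0 || abs(r - round(r)) > 1e-9)
      stop("time$dt_tumor_min must be a positive integer multiple of time$dt_immune_min")
    if (tm$t_end_days <= 0) stop("time$t_end_days must be positive")
    if (init$n_tumor < 0) stop("init$n_tumor must be >= 0")
    if (init$n_tumor > prod(la$dims)) stop("init$n_tumor exceeds lattice capacity")
    for (k in c("frac_mutant", "frac_ha"))
      if (init[[k]] < 0 || init[[k]] > 1) stop("init$", k, " must be in [0,1]")
    rates <- c(tu$alpha_T_per_day, tu$alpha_F_per_day, tu$delta_T_per_day,
               tu$sigma_HA, tu$sigma_LA, im$alpha_I_per_day, im$delta_I_per_day,
               im$m_per_min, im$beta_per_min, im$d_a_per_day, im$rho_max_per_day,
               im$r_rec_per_day, isf$diffusion_site2_per_min, isf$decay_per_min)
    if (any(!is.finite(rates)) || any(rates < 0))
      stop("all rate parameters must be finite and nonnegative")
    if (tu$eps_F < 0 || tu$eps_F >= 1) stop("tumor$eps_F must be in [0, 1)")
    if (tu$sigma_LA >= tu$sigma_HA)
      stop("tumor$sigma_HA must exceed tumor$sigma_LA (HA cells secrete more ISF)")
    if (tu$crowd_threshold < 0 || tu$crowd_threshold > 26)
      stop("tumor$crowd_threshold must be in 0..26")
    if (im$T_perforin_min >= im$T_fas_min)
      stop("immune$T_perforin_min must be less than immune$T_fas_min")
    if (im$hill_h < 1) stop("immune$hill_h must be >= 1")
    if (im$s_max < 0 || im$s_max > 1) stop("immune$s_max must be in [0,1]")
    if (im$n_move < 1) stop("immune$n_move must be >= 1")
    if (!fgfr3$phi_normalization %in% c("half", "total"))
      stop("fgfr3$phi_normalization must be 'half' or 'total'")
    if (!therapy$arm %in% THERAPY_ARMS)
      stop("therapy$arm must be one of: ", paste(THERAPY_ARMS, collapse = ", "))
    for (d in c("smi", "antibody")) {
      p <- pk[[d]]
      if (p$half_life_min <= 0) stop("pk$", d, "$half_life_min must be positive")
      if (any(c(p$k12_per_min, p$k21_per_min, p$k_tme_per_min, p$dose_amount) < 0))
        stop("pk$", d, " rates and dose must be nonnegative")
    }
  })
  cfg$lattice$dims <- as.integer(cfg$lattice$dims)
  cfg$init$n_tumor <- as.integer(cfg$init$n_tumor)
  cfg
}

# Recursive unknown-key check against the default schema.
#' @keywords internal
check_keys <- function(raw, def, path) {
  if (!is.list(raw)) return(invisible())
  nm <- names(raw)
  if (length(raw) && (is.null(nm) || any(nm == "")))
    stop("configuration entries must be named (at ",
         if (length(path)) paste(path, collapse = "$") else "top level", ")")
  for (k in nm) {
    full <- paste(c(path, k), collapse = "$")
    if (!k %in% names(def)) stop("unknown configuration key: ", full)
    if (is.null(raw[[k]])) stop("configuration key ", full, " has no value")
    if (is.list(def[[k]])) check_keys(raw[[k]], def[[k]], c(path, k))
  }
  invisible()
}

#' Build a configuration from named overrides
#'
#' Convenience wrapper around [validate_config()]:
#' `tme_config(tumor = list(alpha_F_per_day = 0), therapy = list(arm = "ICI"))`.
#'
#' @param ... named top-level sections holding partial override lists.
#' @return completed, validated configuration.
#' @export
tme_config <- function(...) {
  validate_config(list(...))
}

#' Read a configuration from a YAML file
#'
#' @param path YAML file with any subset of the keys of [default_config()].
#' @return completed, validated configuration.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validate_config(yaml::read_yaml(path))
}

#' Write a configuration to a YAML file
#'
#' @param config configuration list.
#' @param path output file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
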