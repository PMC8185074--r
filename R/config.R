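#' Default configuration for scoring, closure and design
#'
#' All tunable weights, cutoffs and thresholds used across the toolkit.
#' Values can be overridden per call via `ax_config(...)`.
#'
#' Energy weights apply to the surrogate all-atom function (unitless,
#' kcal/mol-like scale). Interface thresholds: the shape-complementarity
#' cutoff (`sc_min` = 0.65) is scale-free and transfers directly from
#' practice; the binding-energy cutoff (`ddg_max` = -10) is applied on the
#' surrogate scale and is a calibration knob, not a physical constant.
#'
#' @param ... named overrides of any default entry
#' @return named list of configuration values
#' @export
ax_config <- function(...) {
  cfg <- list(
    ## energy weights
    w_rep = 0.55, w_atr = 1.0, w_hb = 1.2, w_rama = 0.4,
    w_zn = 20.0, w_elec = 1.0,
    ## closure restraint weight for cyclic poses (per Angstrom^2 / rad^2)
    w_closure = 100.0,
    ## nonbonded parameters
    lj_eps = 0.15, nb_cutoff = 10.0,
    hb_ideal = 2.9, hb_sd = 0.3, hb_max = 3.5, hb_depth = 1.0,
    elec_eps = 10.0, elec_kappa = 10.0,
    ## geometry / closure
    ideal_cn = 1.328, closure_tol_len = 0.02, closure_tol_ang = 5.0,
    omega_default = 180, omega_jitter = 0,
    ## solution filters (macrocycle sampling)
    rama_cutoff = 5.0, min_genkic_hbonds = 2, min_final_hbonds = 2,
    genkic_closure_attempts = 250,
    ## interface metrics
    contact_cutoff = 4.5, clash_overlap = 0.5,
    sasa_probe = 1.4, sasa_buried = 5.0, hbond_partner_max = 3.5,
    sc_density = 5, sc_weight = 0.5, sc_band = 1.5, sc_probe = 1.4,
    ## zinc coordination
    zn_target = 2.3,
    ## design filters
    sc_min = 0.65, ddg_max = -10, top_frac = 0.01,
    ## design Monte Carlo
    mc_t_start = 3.0, mc_t_end = 0.3,
    ## funnel analysis
    pnear_lambda = 1.5, pnear_kT = 1.0, near_cutoff = 1.5
  )
  ov <- list(...)
  if (length(ov) == 1 && is.null(names(ov)) && is.list(ov[[1]])) ov <- ov[[1]]
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg
}
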