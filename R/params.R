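#' Full simulator parameter set
#'
#' Collects every model constant in one nested list. Values published with
#' the model (channel counts, the CDI rate constant, the dyadic CaM buffer
#' constants, the beta-adrenergic scalings, the spark thresholds) carry
#' provenance `"paper"`; everything else (compartment volumes, diffusion and
#' refill time constants, membrane conductances, buffer on/off rates,
#' voltage-rate coefficients) is `"calibrated"` — tuned so that the resting
#' cell is stable near -80 mV, dyadic Ca2+ during release is roughly two
#' orders of magnitude above myoplasmic Ca2+, spontaneous spark durations are
#' in the low tens of ms, and 1 Hz wild-type pacing gives a regular train of
#' transients. Use [param_provenance()] for the tagged table.
#'
#' @param variant A [cam_variant()] (or anything accepted by
#'   [as_cam_variant()]); its `cdi_factor` scales the LCC O2 -> C4 rate.
#' @param ... Named overrides of any top-level group (`lcc`, `ryr`, `cam`,
#'   `geometry`, `buffers`, `serca`, `membrane`, `dhpr_nj`, `dt_control`,
#'   `init`); each override is a named list merged over the defaults.
#' @return A `crusim_params` nested list.
#' @examples
#' p <- default_params(variant = "mut75")
#' p$variant$cdi_factor
#' @export
default_params <- function(variant = "WT", ...) {
  variant <- as_cam_variant(variant)
  p <- list(
    variant = unclass(variant),
    cam = unclass(cam_kinetics()),                  # paper, Table of buffers
    lcc = unclass(lcc_params()),
    ryr = unclass(ryr_params()),
    geometry = list(
      v_myo_pl  = 25,      # bulk myoplasm volume, pL            [calibrated]
      v_nsr_pl  = 1.5,     # network SR volume, pL               [calibrated]
      v_ds_pl   = 1e-6,    # dyadic subspace volume per CRU, pL  [calibrated]
      v_jsr_pl  = 4e-6,    # junctional SR volume per CRU, pL    [calibrated]
      n_cru_full = 20000,  # CRUs in the full-scale cell         [paper]
      beta_jsr  = 0.1,     # jSR free fraction (calsequestrin)   [calibrated]
      tau_efflux = 3e-5,   # dyad -> myoplasm diffusion time, s  [calibrated]
      tau_refill = 0.03    # NSR -> jSR refill time, s           [calibrated]
    ),
    buffers = list(                                  # single-site mass action
      myo = list(total = 112, k_on = 40,  k_off = 40),    # [calibrated]
      sl  = list(total = 100, k_on = 115, k_off = 1000),  # [calibrated]
      srm = list(total = 47,  k_on = 115, k_off = 100)    # [calibrated]
    ),
    serca = list(vmax = 450, km = 0.35, hill = 2, k_leak = 0.02,
                 nsr_max = 1400, load_hill = 4),
    membrane = list(
      cm = 100,            # pF
      g_na = 13, g_to = 0.35, g_ss = 0.07, g_k1 = 0.45,
      g_bca = 0.0016, g_bna = 0.0024,
      i_nak_max = 0.95, km_nai = 10, km_ko = 1.5,
      k_ncx = 2000, eta_ncx = 0.35, ksat_ncx = 0.1,
      km_na_ncx = 87.5, km_ca_ncx = 1.38,
      g_pca = 0.06, km_pca = 0.5,
      na_o = 140, k_o = 5.4, ca_o_mM = 1.8, rtf = 26.7
    ),
    dhpr_nj = list(fraction = 0.15,  # non-junctional DHPR share   [paper]
                   nu = 250,         # flux scale, uM/s            [calibrated]
                   v_half = -5, v_slope = 7),
    dt_control = list(dt_min = 1e-7, dt_max = 2e-5, dt_init = 1e-6,
                      grow = 1.15, shrink = 0.5,
                      max_frac_cru = 0.10,   # the <=10%-of-CRUs rule [paper]
                      max_rel_inc = 0.2, max_dv = 0.5),
    init = list(v = -83.9, ca_myo = 0.11, ca_nsr = 1000,
                na_i = 10, k_i = 140, ca_ds = 0.11, ca_jsr = 1000)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(p)) stop("default_params: unknown parameter group '", nm, "'")
    if (!is.list(over[[nm]])) stop("default_params: override for '", nm, "' must be a list")
    bad <- setdiff(names(over[[nm]]), names(p[[nm]]))
    if (length(bad)) stop("default_params: unknown keys in '", nm, "': ",
                          paste(bad, collapse = ", "))
    p[[nm]][names(over[[nm]])] <- over[[nm]]
  }
  class(p) <- "crusim_params"
  p
}

#' Provenance of the default parameters
#'
#' @return A data frame with columns `parameter`, `value`, `provenance`
#'   (`"paper"` or `"calibrated"`) for the defaults that anchor the model.
#' @export
param_provenance <- function() {
  p <- default_params()
  rows <- list(
    c("lcc.k24_base",        p$lcc$k24_base,        "paper"),
    c("lcc.n_lcc",           p$lcc$n_lcc,           "paper"),
    c("ryr.n_ryr",           p$ryr$n_ryr,           "paper"),
    c("cam.cam_total",       p$cam$cam_total,       "paper"),
    c("cam.k_on",            p$cam$k_on,            "paper"),
    c("cam.k_off",           p$cam$k_off,           "paper"),
    c("geometry.n_cru_full", p$geometry$n_cru_full, "paper"),
    c("dhpr_nj.fraction",    p$dhpr_nj$fraction,    "paper"),
    c("dt_control.max_frac_cru", p$dt_control$max_frac_cru, "paper"),
    c("lcc.cdi_hill",        p$lcc$cdi_hill,        "paper"),
    c("geometry.v_myo_pl",   p$geometry$v_myo_pl,   "calibrated"),
    c("geometry.tau_efflux", p$geometry$tau_efflux, "calibrated"),
    c("geometry.tau_refill", p$geometry$tau_refill, "calibrated"),
    c("ryr.k_open_base",     p$ryr$k_open_base,     "calibrated"),
    c("ryr.k_close",         p$ryr$k_close,         "calibrated"),
    c("serca.vmax",          p$serca$vmax,          "calibrated"),
    c("membrane.g_na",       p$membrane$g_na,       "calibrated")
  )
  out <- data.frame(parameter = vapply(rows, `[[`, "", 1),
                    value = as.numeric(vapply(rows, `[[`, "", 2)),
                    provenance = vapply(rows, `[[`, "", 3),
                    stringsAsFactors = FALSE)
  out
}
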