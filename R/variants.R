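#' Calmodulin variant descriptor
#'
#' A calmodulin (CaM) variant is characterised by its Ca2+-binding affinity
#' when engaged with the L-type channel and by the multiplicative factor it
#' applies to the channel's Ca:CaM-dependent inactivation rate constant
#' (`k24`). When `cdi_factor` is not supplied it is derived from the affinity
#' via [cdi_factor_from_affinity()] at a reference dyadic Ca2+ of 10 uM
#' against the wild-type affinity.
#'
#' @param name Character label, e.g. `"WT"`, `"D96V"`, or `"mut75"`.
#' @param kd_ca Ca2+-binding affinity in uM (must be > 0). May be `NA` when an
#'   explicit `cdi_factor` is given (e.g. for the synthetic `mut90`/`mut75`
#'   rate-scaling mutants, which are defined by their factor, not an affinity).
#' @param cdi_factor Optional explicit multiplier on `k24`, in (0, 1]. If
#'   `NULL`, derived from `kd_ca`.
#' @param kd_wt Wild-type reference affinity in uM (default 2.5).
#' @param ca_ref Reference dyadic Ca2+ in uM at which the bound-CaM ratio is
#'   evaluated (default 10).
#'
#' @return An object of class `cam_variant`: a list with fields `name`,
#'   `kd_ca`, `cdi_factor`.
#' @examples
#' cam_variant("D96V", kd_ca = 38.0)   # cdi_factor 0.74
#' cam_variant("mut75", cdi_factor = 0.75)
#' @export
cam_variant <- function(name, kd_ca = NA_real_, cdi_factor = NULL,
                        kd_wt = 2.5, ca_ref = 10) {
  stopifnot(is.character(name), length(name) == 1L)
  if (is.null(cdi_factor)) {
    if (!is.finite(kd_ca)) {
      stop("cam_variant: need either a finite `kd_ca` or an explicit `cdi_factor`")
    }
    cdi_factor <- cdi_factor_from_affinity(kd_ca, kd_wt = kd_wt, ca_dyad = ca_ref)
  }
  if (!is.finite(cdi_factor) || cdi_factor <= 0 || cdi_factor > 1) {
    stop("cam_variant: cdi_factor must lie in (0, 1], got ", cdi_factor)
  }
  if (is.finite(kd_ca) && kd_ca <= 0) stop("cam_variant: kd_ca must be > 0")
  if (identical(name, "WT") && abs(cdi_factor - 1) > 1e-12) {
    stop("cam_variant: the wild type must have cdi_factor exactly 1")
  }
  structure(list(name = name, kd_ca = kd_ca, cdi_factor = cdi_factor),
            class = "cam_variant")
}

#' @export
print.cam_variant <- function(x, ...) {
  cat(sprintf("<cam_variant> %s  Kd(Ca) = %s uM  CDI factor = %.4f x k24\n",
              x$name, ifelse(is.finite(x$kd_ca), format(x$kd_ca), "--"),
              x$cdi_factor))
  invisible(x)
}

#' CDI multiplier from a variant's Ca2+-binding affinity
#'
#' The effector of Ca2+-dependent inactivation (CDI) is Ca2+-bound calmodulin.
#' At steady state of the mass-action binding scheme the bound fraction at
#' dyadic Ca2+ concentration `ca` is `ca^2 / (ca^2 + K)`, with the affinity
#' `K` entered at its printed uM value (numeric convention of the source
#' model; `ca^2` is in uM^2). The multiplier applied to the inactivation rate
#' constant `k24` is the ratio of the variant's bound fraction to the
#' wild type's:
#'
#' `factor = (ca^2 + kd_wt) / (ca^2 + kd_variant)`
#'
#' Evaluated at the conventional dyadic Ca2+ of 10 uM and wild-type affinity
#' 2.5 uM this reproduces the published multipliers for the disease variants
#' (e.g. D96V: 0.74, N98S: 0.92, D130G: 0.41).
#'
#' @param kd_variant Variant affinity, uM (> 0).
#' @param kd_wt Wild-type affinity, uM (> 0; default 2.5).
#' @param ca_dyad Dyadic Ca2+ at which the ratio is taken, uM (> 0; default 10).
#' @return Dimensionless multiplier (1 when `kd_variant == kd_wt`).
#' @examples
#' cdi_factor_from_affinity(38.0)   # 0.74 (D96V)
#' cdi_factor_from_affinity(150.0)  # 0.41 (D130G)
#' @export
cdi_factor_from_affinity <- function(kd_variant, kd_wt = 2.5, ca_dyad = 10) {
  if (any(!is.finite(kd_variant)) || any(kd_variant <= 0)) {
    stop("cdi_factor_from_affinity: kd_variant must be finite and > 0")
  }
  if (!is.finite(kd_wt) || kd_wt <= 0) stop("cdi_factor_from_affinity: kd_wt must be > 0")
  if (!is.finite(ca_dyad) || ca_dyad <= 0) stop("cdi_factor_from_affinity: ca_dyad must be > 0")
  ca2 <- ca_dyad^2
  (ca2 + kd_wt) / (ca2 + kd_variant)
}

#' Ca:CaM binding kinetics
#'
#' Parameter container for the mass-action binding of two Ca2+ ions to dyadic
#' calmodulin. Defaults are the published buffer constants: total CaM 24 uM,
#' on-rate 30 uM^-1 s^-1 (applied to Ca^2, see [cam_binding_rhs()]), off-rate
#' 71.4 s^-1.
#'
#' @param cam_total Total dyadic CaM, uM.
#' @param k_on Association constant (multiplies Ca^2 in uM^2), s^-1 uM^-2
#'   numerically applied as printed.
#' @param k_off Dissociation rate, s^-1.
#' @return A `cam_kinetics` list with the fields plus `keq = k_off / k_on` (uM
#'   convention).
#' @export
cam_kinetics <- function(cam_total = 24, k_on = 30, k_off = 71.4) {
  stopifnot(cam_total > 0, k_on > 0, k_off > 0)
  structure(list(cam_total = cam_total, k_on = k_on, k_off = k_off,
                 keq = k_off / k_on),
            class = "cam_kinetics")
}

#' Rate of change of dyadic Ca:CaM
#'
#' Mass-action kinetics with two-Ca2+ stoichiometry:
#' `d[Ca:CaM]/dt = k_on * ca^2 * (cam_total - ca_cam) - k_off * ca_cam`.
#'
#' @param ca_dyad Dyadic free Ca2+, uM (>= 0).
#' @param ca_cam Current Ca:CaM, uM; must lie in `[0, cam_total]`.
#' @param kinetics A [cam_kinetics()] object.
#' @return d\[Ca:CaM\]/dt in uM/s.
#' @examples
#' k <- cam_kinetics()
#' cam_binding_rhs(0, 5, k)    # pure dissociation: -357 uM/s
#' @export
cam_binding_rhs <- function(ca_dyad, ca_cam, kinetics = cam_kinetics()) {
  if (any(ca_dyad < 0)) stop("cam_binding_rhs: ca_dyad must be >= 0")
  if (any(ca_cam < 0) || any(ca_cam > kinetics$cam_total)) {
    stop("cam_binding_rhs: ca_cam must lie in [0, cam_total]")
  }
  kinetics$k_on * ca_dyad^2 * (kinetics$cam_total - ca_cam) -
    kinetics$k_off * ca_cam
}

#' Steady-state dyadic Ca:CaM
#'
#' Closed form of the binding scheme at fixed dyadic Ca2+:
#' `ca^2 * cam_total / (ca^2 + keq)` with `keq = k_off / k_on`.
#'
#' @inheritParams cam_binding_rhs
#' @return Equilibrium Ca:CaM, uM.
#' @export
cam_equilibrium <- function(ca_dyad, kinetics = cam_kinetics()) {
  if (any(ca_dyad < 0)) stop("cam_equilibrium: ca_dyad must be >= 0")
  ca2 <- ca_dyad^2
  ca2 * kinetics$cam_total / (ca2 + kinetics$keq)
}

#' Read a calmodulin variant table
#'
#' Reads a delimited text table with columns `name`, `kd_ca_uM` and optional
#' `cdi_factor` (an explicit override of the affinity-derived factor). The
#' package ships the published disease-variant table in
#' `system.file("extdata", "cam_variants.csv", package = "crusim")`.
#'
#' @param path Path to a CSV file; default the bundled table.
#' @param kd_wt,ca_ref Passed to [cam_variant()].
#' @return A named list of [cam_variant()] objects.
#' @examples
#' vs <- read_variant_table()
#' round(vapply(vs, `[[`, numeric(1), "cdi_factor"), 2)
#' @export
read_variant_table <- function(path = system.file("extdata", "cam_variants.csv",
                                                  package = "crusim"),
                               kd_wt = 2.5, ca_ref = 10) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "kd_ca_uM")
  if (!all(need %in% names(tab))) {
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    cf <- if ("cdi_factor" %in% names(tab) && is.finite(tab$cdi_factor[i])) {
      tab$cdi_factor[i]
    } else NULL
    cam_variant(tab$name[i], kd_ca = tab$kd_ca_uM[i], cdi_factor = cf,
                kd_wt = kd_wt, ca_ref = ca_ref)
  })
  names(out) <- tab$name
  out
}

#' Resolve a variant argument to a `cam_variant`
#'
#' Accepts a `cam_variant`, one of the bundled names (`"WT"`, `"D96V"`, ...),
#' the rate-scaling mutants `"mut90"` / `"mut75"` used throughout the pacing
#' experiments (CDI factors 0.90 and 0.75), or a bare numeric CDI factor.
#'
#' @param variant Variant specification (see Details).
#' @return A `cam_variant`.
#' @export
as_cam_variant <- function(variant) {
  if (inherits(variant, "cam_variant")) return(variant)
  if (is.numeric(variant) && length(variant) == 1L) {
    nm <- if (abs(variant - 1) < 1e-12) "WT" else sprintf("cdi%.2f", variant)
    return(cam_variant(nm, cdi_factor = variant))
  }
  if (is.character(variant) && length(variant) == 1L) {
    if (variant == "mut90") return(cam_variant("mut90", cdi_factor = 0.90))
    if (variant == "mut75") return(cam_variant("mut75", cdi_factor = 0.75))
    tab <- read_variant_table()
    if (variant %in% names(tab)) return(tab[[variant]])
    stop("unknown variant name: ", variant)
  }
  stop("cannot interpret `variant`; give a cam_variant, a name, or a factor")
}
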