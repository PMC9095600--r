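#' Crop parameter set for the winter-wheat simulator
#'
#' Builds the biological constant set driving [run_season()]. Defaults are a
#' documented winter-wheat set in the units stated below; every value can be
#' overridden, and the calibration layer treats a configurable subset of them
#' as free parameters.
#'
#' @param TSUM1 Thermal time from emergence to anthesis (degC d).
#' @param TSUM2 Thermal time from anthesis to maturity (degC d).
#' @param TDWI Initial total crop dry weight at emergence (kg/ha).
#' @param SPAN Leaf life span at a reference temperature of 35 degC (d).
#' @param SLA Specific leaf area (ha/kg).
#' @param RGRLAI Relative LAI growth rate in the juvenile phase (per degC d).
#' @param k_ext Light extinction coefficient (dimensionless).
#' @param eps_lue Light-use efficiency on intercepted PAR, in kg dry matter
#'   per hectare per MJ/m2 of PAR (30 here corresponds to 3.0 g/MJ).
#' @param rm_leaf,rm_stem,rm_storage,rm_root Maintenance respiration
#'   coefficients at 25 degC (per day, per unit biomass).
#' @param q10 Relative respiration increase per 10 degC (dimensionless).
#' @param tbase_pheno Base temperature for thermal time (degC).
#' @param dvs_juvenile DVS below which leaf-area growth is limited by the
#'   exponential juvenile rule rather than by assimilate supply alone.
#' @param part_table data.frame with columns `dvs`, `leaf`, `stem`,
#'   `storage`, `root`: piecewise-linear partitioning fractions of net growth,
#'   each row summing to 1.
#' @return An object of class `crop_params` (a validated named list).
#' @export
crop_params <- function(TSUM1 = 1000, TSUM2 = 800, TDWI = 210, SPAN = 30,
                        SLA = 0.0021, RGRLAI = 0.0082, k_ext = 0.6,
                        eps_lue = 24, rm_leaf = 0.025, rm_stem = 0.008,
                        rm_storage = 0.003, rm_root = 0.01, q10 = 2,
                        tbase_pheno = 0, dvs_juvenile = 0.3,
                        part_table = default_part_table()) {
  p <- list(tsum1 = TSUM1, tsum2 = TSUM2, tdwi = TDWI, span = SPAN,
            sla = SLA, rgrlai = RGRLAI, k_ext = k_ext, eps_lue = eps_lue,
            rm_leaf = rm_leaf, rm_stem = rm_stem, rm_storage = rm_storage,
            rm_root = rm_root, q10 = q10, tbase_pheno = tbase_pheno,
            dvs_juvenile = dvs_juvenile,
            part_dvs = part_table$dvs, part_leaf = part_table$leaf,
            part_stem = part_table$stem, part_storage = part_table$storage,
            part_root = part_table$root)
  validate_crop_params(p)
  structure(p, class = "crop_params")
}

#' Default partitioning table for winter wheat
#'
#' Fractions of daily net growth allocated to leaves, stems, storage organs
#' and roots as piecewise-linear functions of DVS; each row sums to 1.
#'
#' @return data.frame with columns dvs, leaf, stem, storage, root.
#' @export
default_part_table <- function() {
  data.frame(
    dvs     = c(0.0, 0.4, 0.8, 1.0, 1.2, 2.0),
    leaf    = c(0.35, 0.30, 0.15, 0.05, 0.00, 0.00),
    stem    = c(0.25, 0.45, 0.65, 0.25, 0.05, 0.00),
    storage = c(0.00, 0.00, 0.00, 0.65, 0.95, 1.00),
    root    = c(0.40, 0.25, 0.20, 0.05, 0.00, 0.00)
  )
}

validate_crop_params <- function(p) {
  pos <- c("tsum1", "tsum2", "tdwi", "span", "sla", "rgrlai", "k_ext",
           "eps_lue", "q10")
  for (nm in pos) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("crop parameter '", nm, "' must be finite and > 0", call. = FALSE)
  }
  for (nm in c("rm_leaf", "rm_stem", "rm_storage", "rm_root"))
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      stop("crop parameter '", nm, "' must be finite and >= 0", call. = FALSE)
  fr <- cbind(p$part_leaf, p$part_stem, p$part_storage, p$part_root)
  if (any(fr < 0) || any(fr > 1))
    stop("partitioning fractions must lie in [0, 1]", call. = FALSE)
  if (any(abs(rowSums(fr) - 1) > 1e-8))
    stop("partitioning fractions must sum to 1 at every DVS node",
         call. = FALSE)
  if (is.unsorted(p$part_dvs, strictly = TRUE))
    stop("part_table dvs nodes must be strictly increasing", call. = FALSE)
  invisible(p)
}

#' Soil water-retention parameters
#'
#' @param sm_wilt,sm_fc,sm_sat Volumetric soil moisture at wilting point,
#'   field capacity and saturation (fractions, 0 < wilt < fc < sat < 1).
#' @param root_depth Rooted soil depth (cm) over which the water bucket and
#'   irrigation applications are spread.
#' @param sm_crit_frac Fraction locating the transpiration stress-onset
#'   moisture between wilting point and field capacity.
#' @return An object of class `soil_params`.
#' @export
soil_params <- function(sm_wilt = 0.12, sm_fc = 0.30, sm_sat = 0.45,
                        root_depth = 100, sm_crit_frac = 0.5) {
  if (!(sm_wilt > 0 && sm_wilt < sm_fc && sm_fc < sm_sat && sm_sat < 1))
    stop("require 0 < sm_wilt < sm_fc < sm_sat < 1", call. = FALSE)
  if (root_depth <= 0) stop("root_depth must be > 0", call. = FALSE)
  if (sm_crit_frac <= 0 || sm_crit_frac > 1)
    stop("sm_crit_frac must lie in (0, 1]", call. = FALSE)
  structure(list(sm_wilt = sm_wilt, sm_fc = sm_fc, sm_sat = sm_sat,
                 root_depth = root_depth, sm_crit_frac = sm_crit_frac),
            class = "soil_params")
}

#' Threshold-triggered irrigation policy
#'
#' An irrigation event of depth `V` cm is applied on any day whose
#' start-of-day soil moisture is strictly below the trigger `SMc`.
#'
#' @param SMc Volumetric soil-moisture trigger threshold.
#' @param V Application depth per event (cm of water).
#' @param enabled Logical; a disabled policy never irrigates.
#' @param soil Optional `soil_params` used to check that `SMc` lies between
#'   wilting point and saturation.
#' @return An object of class `irrigation_policy`.
#' @export
irrigation_policy <- function(SMc = 0.2, V = 4, enabled = TRUE, soil = NULL) {
  if (V < 0) stop("irrigation depth V must be >= 0", call. = FALSE)
  if (enabled && !is.null(soil) && (SMc < soil$sm_wilt || SMc > soil$sm_sat))
    stop("SMc must lie within [sm_wilt, sm_sat]", call. = FALSE)
  structure(list(SMc = SMc, V = V, enabled = isTRUE(enabled)),
            class = "irrigation_policy")
}

#' @export
print.crop_params <- function(x, ...) {
  cat("Winter-wheat crop parameters\n")
  cat(sprintf("  TSUM1 %.0f  TSUM2 %.0f degC d;  TDWI %.0f kg/ha;  SPAN %.1f d\n",
              x$tsum1, x$tsum2, x$tdwi, x$span))
  cat(sprintf("  SLA %.4g ha/kg;  RGRLAI %.4g /degC d;  k %.2f;  LUE %.3g kg/ha per MJ/m2 PAR\n",
              x$sla, x$rgrlai, x$k_ext, x$eps_lue))
  invisible(x)
}

#' @export
print.irrigation_policy <- function(x, ...) {
  if (x$enabled)
    cat(sprintf("Irrigation: trigger SMc = %.3f, depth V = %.2f cm\n",
                x$SMc, x$V))
  else cat("Irrigation: disabled (rainfed)\n")
  invisible(x)
}

# Replace a named subset of crop parameters, revalidating.
set_crop_params <- function(crop, values) {
  map <- c(TSUM1 = "tsum1", TSUM2 = "tsum2", TDWI = "tdwi", SPAN = "span",
           SLA = "sla", RGRLAI = "rgrlai", k_ext = "k_ext",
           eps_lue = "eps_lue", tbase_pheno = "tbase_pheno")
  for (nm in names(values)) {
    key <- if (nm %in% names(map)) map[[nm]] else nm
    if (!key %in% names(crop))
      stop("unknown crop parameter '", nm, "'", call. = FALSE)
    crop[[key]] <- as.numeric(values[[nm]])
  }
  validate_crop_params(crop)
  crop
}

# Read a crop parameter by its user-facing name.
get_crop_param <- function(crop, name) {
  map <- c(TSUM1 = "tsum1", TSUM2 = "tsum2", TDWI = "tdwi", SPAN = "span",
           SLA = "sla", RGRLAI = "rgrlai", k_ext = "k_ext",
           eps_lue = "eps_lue", tbase_pheno = "tbase_pheno")
  key <- if (name %in% names(map)) map[[name]] else name
  crop[[key]]
}
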