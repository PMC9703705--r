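#' Normalize a raw gas-exchange flux by area
#'
#' Divides a whole-organ flux (gas amount per second) by the
#' normalization area in cm^2, converting to the per-m^2 convention of
#' leaf-chamber instruments (1 m^2 = 10^4 cm^2). For panicles the
#' normalization area is the projected panicle area (PPA) from the 3D
#' reconstruction; for leaves it is the chamber aperture area.
#'
#' @param raw_flux numeric flux per organ (e.g. µmol CO2 s^-1).
#' @param area_cm2 positive normalization area in cm^2.
#' @return Per-area flux (e.g. µmol CO2 m^-2 s^-1). Vectorized.
#' @examples
#' normalize_flux(3, 50)  # 3 / 0.005 m^2 = 600
#' @export
normalize_flux <- function(raw_flux, area_cm2) {
  if (any(!is.finite(area_cm2)) || any(area_cm2 <= 0))
    stop("'area_cm2' must be positive")
  raw_flux / (area_cm2 / 1e4)
}

#' Water use efficiency
#'
#' WUE = A / E, carbon assimilation divided by apparent transpiration,
#' both on the same per-area basis.
#'
#' @param A per-area carbon assimilation.
#' @param E per-area apparent transpiration; must be non-zero.
#' @return A / E. Vectorized.
#' @export
wue <- function(A, E) {
  if (any(E == 0, na.rm = TRUE))
    stop("WUE undefined: transpiration E is 0")
  A / E
}

#' Percent change of a treated value against its control
#'
#' Signed percent change `100 * (treated - control) / control`, as used
#' to compare heat-stressed assimilation rates against the paired
#' control means.
#'
#' @param treated,control numeric; `control` must be non-zero.
#' @return Signed percentage. Vectorized.
#' @examples
#' percent_change(2.21, 1)  # +121
#' percent_change(0.44, 1)  # -56
#' @export
percent_change <- function(treated, control) {
  if (any(control == 0, na.rm = TRUE))
    stop("percent change undefined: control value is 0")
  100 * (treated - control) / control
}

#' Percent fertility from seed counts
#'
#' `100 * filled / (filled + sterile)`, the share of fully developed
#' seeds among all scored seeds (fully developed plus completely
#' sterile).
#'
#' @param n_filled,n_sterile non-negative counts; their sum must be at
#'   least 1.
#' @return Percentage in `[0, 100]`. Vectorized.
#' @export
percent_fertility <- function(n_filled, n_sterile) {
  if (any(n_filled < 0) || any(n_sterile < 0))
    stop("seed counts must be non-negative")
  tot <- n_filled + n_sterile
  if (any(tot < 1))
    stop("percent fertility undefined: no seeds scored")
  100 * n_filled / tot
}

#' Pairwise Pearson correlation panel
#'
#' Computes the pairwise Pearson correlation matrix over a set of
#' digital and gas-exchange traits, with p-values from the t
#' transform of r at n - 2 degrees of freedom. Intended to be run per
#' genotype x treatment x timepoint stratum (replicates as rows), the
#' layout used to relate PPA, VC and green proportion to A and E of
#' panicle and flag leaf. Zero-variance traits yield `NA` correlations
#' and are flagged, never silently zeroed.
#'
#' @param traits_table data.frame or matrix, replicates in rows and
#'   traits in columns.
#' @param traits optional character vector selecting/ordering columns.
#' @return An object of class `pearson_panel`: list with `r`
#'   (correlation matrix), `p` (p-value matrix, `NA` diagonal), `n`
#'   (number of replicates) and `degenerate` (names of zero-variance
#'   traits).
#' @export
pearson_panel <- function(traits_table, traits = NULL) {
  x <- as.data.frame(traits_table)
  if (!is.null(traits)) {
    missing <- setdiff(traits, names(x))
    if (length(missing))
      stop("traits not found in table: ", paste(missing, collapse = ", "))
    x <- x[traits]
  }
  x <- x[vapply(x, is.numeric, logical(1))]
  if (ncol(x) < 2L)
    stop("need at least two numeric traits")
  n <- nrow(x)
  if (n < 3L)
    stop("need at least 3 replicates for a correlation panel")
  m <- as.matrix(x)
  sds <- apply(m, 2, sd)
  degen <- colnames(m)[!is.na(sds) & sds == 0]
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  diag(r) <- ifelse(colnames(m) %in% degen, NA_real_, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  p[is.na(r)] <- NA_real_
  diag(p) <- NA_real_
  structure(list(r = r, p = p, n = n, degenerate = degen),
            class = "pearson_panel")
}

#' @export
print.pearson_panel <- function(x, digits = 2, ...) {
  cat(sprintf("Pearson correlation panel (%d replicates)\n", x$n))
  print(round(x$r, digits))
  if (length(x$degenerate))
    cat("zero-variance traits:", paste(x$degenerate, collapse = ", "),
        "\n")
  invisible(x)
}

#' Correlation panels per experimental stratum
#'
#' Splits a long replicate table by stratum columns (default genotype,
#' treatment and timepoint) and computes one [pearson_panel()] per
#' stratum with enough replicates.
#'
#' @param data data.frame with one row per replicate.
#' @param traits character vector of trait columns to correlate.
#' @param by character vector of stratum columns present in `data`.
#' @return Named list of `pearson_panel` objects, one per stratum.
#' @export
correlate_by_stratum <- function(data,
                                 traits,
                                 by = c("genotype", "treatment", "daf")) {
  data <- as.data.frame(data)
  by <- intersect(by, names(data))
  if (!length(by))
    return(list(all = pearson_panel(data, traits)))
  key <- interaction(data[by], sep = ":", drop = TRUE)
  out <- lapply(split(data, key), function(d) {
    if (nrow(d) < 3L) return(NULL)
    pearson_panel(d, traits)
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Read and normalize a gas-exchange table
#'
#' Reads a CSV of gas-exchange records with label columns (`tissue`,
#' `genotype`, `treatment`, `daf`) and either raw fluxes plus a
#' normalization area (`A_raw`, `E_raw`, `area_cm2`) or fluxes already
#' on a per-area basis (`A`, `E`). Raw fluxes are normalized per m^2
#' with [normalize_flux()]; a `wue` column (A / E) is appended.
#'
#' @param path CSV file path.
#' @return data.frame with per-area `A`, `E` and `wue` columns.
#' @export
read_gas_exchange <- function(path) {
  if (!file.exists(path)) stop("gas-exchange file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  normalize_gas_exchange(df)
}

#' @rdname read_gas_exchange
#' @param df data.frame in the same layout as the CSV.
#' @export
normalize_gas_exchange <- function(df) {
  df <- as.data.frame(df)
  if (all(c("A_raw", "E_raw", "area_cm2") %in% names(df))) {
    df$A <- normalize_flux(df$A_raw, df$area_cm2)
    df$E <- normalize_flux(df$E_raw, df$area_cm2)
  } else if (!all(c("A", "E") %in% names(df))) {
    stop("need either (A_raw, E_raw, area_cm2) or per-area (A, E) columns")
  }
  df$wue <- wue(df$A, df$E)
  df
}
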