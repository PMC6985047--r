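#' Stratum definitions for molecular and clinical categories
#'
#' ER percent positivity is partitioned as: negative (< 1%), borderline
#' (>= 1 - < 10%), low (>= 10 - < 40%), intermediate (>= 40 - < 80%),
#' high (>= 80%); the very-high (>= 95%) group is a nested subanalysis of
#' the high group, not a sixth partition cell. ESR1 expression is
#' median-centered, standardized, and split into quartiles with any
#' remainder cases allocated to the top quartiles first. Normal-like PAM50
#' tumors are excluded.
#'
#' @name stratification
NULL

er_category_levels <- c("negative", "borderline", "low", "intermediate", "high")

#' Assign ER percent-positivity categories
#'
#' @param er_percent numeric vector in \[0, 100\] (NA allowed, propagated)
#' @return data.frame with `category` (factor: negative, borderline, low,
#'   intermediate, high) and `very_high` (logical, TRUE when >= 95; nested
#'   within high)
#' @export
assign_er_category <- function(er_percent) {
  bad <- !is.na(er_percent) & (er_percent < 0 | er_percent > 100)
  if (any(bad))
    stop("er_percent outside [0, 100] at positions: ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  cat <- cut(er_percent, breaks = c(-Inf, 1, 10, 40, 80, Inf),
             labels = er_category_levels, right = FALSE)
  data.frame(category = cat, very_high = !is.na(er_percent) & er_percent >= 95)
}

#' Clinical ER positivity at a 1% or 10% cut point
#'
#' @param er_percent numeric vector in \[0, 100\]
#' @param cutpoint 1 or 10 (boundary closed: `>= cutpoint` is positive)
#' @return factor with levels `negative`, `positive`
#' @export
assign_clinical_er <- function(er_percent, cutpoint = 1) {
  if (!cutpoint %in% c(1, 10))
    stop("cutpoint must be 1 or 10", call. = FALSE)
  bad <- !is.na(er_percent) & (er_percent < 0 | er_percent > 100)
  if (any(bad)) stop("er_percent outside [0, 100]", call. = FALSE)
  factor(ifelse(er_percent >= cutpoint, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' Median-center and standardize ESR1 expression
#'
#' Values are median-centered, then rescaled to sample mean zero and unit
#' variance. Quartile assignment is invariant to this (affine) transform
#' order.
#'
#' @param esr1_raw numeric vector; NAs are propagated
#' @return standardized values (mean 0, variance 1 over non-missing entries)
#' @export
standardize_esr1 <- function(esr1_raw) {
  ok <- !is.na(esr1_raw)
  if (sum(ok) < 2L || stats::sd(esr1_raw[ok]) == 0)
    stop("need >= 2 non-missing values with nonzero spread", call. = FALSE)
  y <- esr1_raw - stats::median(esr1_raw[ok])
  out <- (y - mean(y[ok])) / stats::sd(y[ok])
  out
}

#' Assign expression quartiles
#'
#' Q1 holds the lowest and Q4 the highest values. Group sizes differ by at
#' most one; when `n mod 4 != 0` the remainder cases are allocated to the
#' top quartiles first (n = 1965 gives Q4 = 492 and Q1-Q3 = 491 each).
#' Ties are broken by stable input order, with a warning.
#'
#' @param values standardized expression values (NA dropped from ranking,
#'   returned as NA)
#' @return factor Q1..Q4, same length as `values`
#' @export
assign_quartiles <- function(values) {
  ok <- which(!is.na(values))
  n <- length(ok)
  if (n < 4L) stop("need >= 4 non-missing values", call. = FALSE)
  v <- values[ok]
  if (anyDuplicated(v))
    warning("ties present; quartile ranks broken by stable input order",
            call. = FALSE)
  r <- rank(v, ties.method = "first")
  base <- n %/% 4L
  rem <- n %% 4L
  sizes <- base + c(rep(0L, 4L - rem), rep(1L, rem))   # extras go to Q4 first
  qs <- cut(r, breaks = c(0, cumsum(sizes)), labels = paste0("Q", 1:4))
  out <- factor(rep(NA_character_, length(values)), levels = paste0("Q", 1:4))
  out[ok] <- qs
  out
}

pam50_alias <- c(
  "luma" = "LumA", "luminala" = "LumA", "luminal a" = "LumA",
  "lumb" = "LumB", "luminalb" = "LumB", "luminal b" = "LumB",
  "her2" = "Her2", "her2enriched" = "Her2", "her2-enriched" = "Her2",
  "basal" = "Basal", "basallike" = "Basal", "basal-like" = "Basal",
  "normal" = "Normal", "normallike" = "Normal", "normal-like" = "Normal"
)

normalize_pam50 <- function(x) {
  key <- gsub("[ _-]", "", tolower(trimws(as.character(x))))
  out <- unname(pam50_alias[key])
  out
}

#' Keep only intrinsic-subtype cases (drop Normal-like and missing)
#'
#' Labels are normalized through an alias table ("Luminal A" == "LumA",
#' etc.). The numbers dropped per reason are reported by message; the
#' operation is idempotent.
#'
#' @param records case data.frame with a `pam50` column
#' @return records restricted to LumA, LumB, Her2, Basal, with `pam50`
#'   normalized
#' @export
filter_pam50 <- function(records) {
  stopifnot("pam50" %in% names(records))
  lab <- normalize_pam50(records$pam50)
  unknown <- !is.na(records$pam50) & is.na(lab)
  if (any(unknown))
    warning("unrecognized PAM50 labels excluded: ",
            paste(unique(records$pam50[unknown]), collapse = ", "), call. = FALSE)
  n_missing <- sum(is.na(records$pam50))
  n_normal <- sum(lab == "Normal", na.rm = TRUE)
  keep <- !is.na(lab) & lab != "Normal"
  message(sprintf("filter_pam50: kept %d; dropped %d Normal-like, %d missing, %d unrecognized",
                  sum(keep), n_normal, n_missing, sum(unknown)))
  if (!any(keep)) warning("no intrinsic-subtype cases remain", call. = FALSE)
  out <- records[keep, , drop = FALSE]
  out$pam50 <- factor(lab[keep], levels = c("LumA", "LumB", "Her2", "Basal"))
  out
}

#' Tumor-characteristic strata (grade, size, nodes)
#'
#' @param records case data.frame
#' @param scheme one of `grade`, `size`, `nodes`
#' @param size_cut tumor-size cut in cm (default 2)
#' @param node_breaks upper bounds defining node groups; default gives
#'   `negative`, `1`, `2+`
#' @return factor of stratum labels (NA for missing/unknown, with warning)
#' @export
assign_tumor_characteristic_strata <- function(records,
                                               scheme = c("grade", "size", "nodes"),
                                               size_cut = 2,
                                               node_breaks = c(0, 1)) {
  scheme <- match.arg(scheme)
  if (scheme == "grade") {
    g <- suppressWarnings(as.integer(as.character(records$grade)))
    bad <- !is.na(records$grade) & (is.na(g) | !g %in% 1:3)
    if (any(bad))
      warning("unknown grade labels excluded: ",
              paste(unique(records$grade[bad]), collapse = ", "), call. = FALSE)
    g[bad | is.na(g)] <- NA_integer_
    factor(paste0("grade_", g), levels = paste0("grade_", 1:3),
           exclude = "grade_NA")
  } else if (scheme == "size") {
    s <- records$tumor_size
    factor(ifelse(is.na(s), NA_character_,
                  ifelse(s < size_cut, "small", "large")),
           levels = c("small", "large"))
  } else {
    nd <- suppressWarnings(as.numeric(as.character(records$node_status)))
    lab <- ifelse(is.na(nd), NA_character_,
                  ifelse(nd <= node_breaks[1], "negative",
                         ifelse(nd <= node_breaks[2], "1", "2+")))
    factor(lab, levels = c("negative", "1", "2+"))
  }
}
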