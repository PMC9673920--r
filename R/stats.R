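#' Paired t test on per-animal PK parameters
#'
#' Two-sided paired t test on the within-animal differences `a - b`, with
#' `df = n - 1`. Glycoforms of one preparation share each animal's physiology,
#' so pairing by animal removes the inter-individual PK variability that
#' dominates total-concentration comparisons.
#'
#' When the differences have zero variance the t statistic is degenerate; the
#' result is flagged (`degenerate = TRUE`, `p = NA`) rather than reported as
#' p = 0.
#'
#' @param a,b Numeric vectors of equal length (>= 2), paired by animal.
#' @return List with elements `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_test <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  n <- length(d)
  if (sd(d) == 0) {
    return(list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                df = n - 1, p = NA_real_, mean_diff = mean(d),
                degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(d), degenerate = FALSE)
}

#' Welch two-sample t test
#'
#' Unpaired two-sided t test without the equal-variance assumption
#' (Welch-Satterthwaite degrees of freedom), as used for serum-profile
#' comparisons between independently dosed groups.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with elements `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
welch_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (sd(a) == 0 && sd(b) == 0) {
    md <- mean(a) - mean(b)
    return(list(t = if (md == 0) 0 else sign(md) * Inf,
                df = NA_real_, p = NA_real_, mean_diff = md,
                degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(a) - mean(b), degenerate = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Implements the BH step-up procedure on one family of p values: sort
#' ascending, find the largest rank `i` with `p_(i) <= (i/m) * fdr`, and
#' reject that test and all with smaller p. `NA` p values stay in the output
#' but are excluded from the family (never rejected, not counted in `m`).
#'
#' @param p Numeric vector of p values in \[0, 1\] (NAs allowed).
#' @param fdr Target false discovery rate (default 0.05).
#' @return Tibble aligned with `p`: columns `p`, `rank`, `alpha_adjusted`
#'   (`rank/m * fdr`, the per-test step-up threshold), and `reject`.
#' @export
bh_adjust <- function(p, fdr = 0.05) {
  stopifnot(fdr > 0, fdr < 1)
  if (length(p) == 0) {
    return(tibble::tibble(p = numeric(), rank = integer(),
                          alpha_adjusted = numeric(), reject = logical()))
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must be in [0, 1]", call. = FALSE)
  ok <- !is.na(p)
  m <- sum(ok)
  rank <- rep(NA_integer_, length(p))
  alpha <- rep(NA_real_, length(p))
  reject <- rep(FALSE, length(p))
  if (m > 0) {
    o <- order(p[ok])
    r <- integer(m); r[o] <- seq_len(m)
    rank[ok] <- r
    alpha[ok] <- r / m * fdr
    passed <- which(sort(p[ok]) <= seq_len(m) / m * fdr)
    if (length(passed) > 0) {
      k <- max(passed)
      rej <- rep(FALSE, m); rej[o[seq_len(k)]] <- TRUE
      reject[ok] <- rej
    }
  }
  tibble::tibble(p = p, rank = rank, alpha_adjusted = alpha, reject = reject)
}

#' Mean, SD and t-based 95% confidence interval
#'
#' @param x Numeric vector, length >= 2.
#' @return List with `n`, `mean`, `sd`, `ci95_low`, `ci95_high` (t
#'   distribution, `df = n - 1`).
#' @export
summarize_values <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least 2 values to summarize", call. = FALSE)
  m <- mean(x); s <- sd(x)
  half <- qt(0.975, df = n - 1) * s / sqrt(n)
  list(n = n, mean = m, sd = s, ci95_low = m - half, ci95_high = m + half)
}

stars_for <- function(p, significant) {
  ifelse(!significant | is.na(p), "",
         ifelse(p < 1e-4, "****",
                ifelse(p < 1e-3, "***",
                       ifelse(p < 0.01, "**", "*"))))
}

#' Compare glycoform clearances against a reference glycoform
#'
#' Within each experimental group (one preparation and route), pairs each
#' glycoform's clearance with the reference glycoform's clearance in the same
#' animal, runs two-sided paired t tests, and applies Benjamini-Hochberg
#' FDR control across the group's family of contrasts. Significance stars
#' follow the conventional tiers (`*` significant, `**` p < 0.01, `***`
#' p < 0.001, `****` p < 0.0001), awarded only to FDR-significant contrasts.
#'
#' Additional ad hoc contrasts (e.g. an oligomannose versus a monoantennary
#' glycoform) can be supplied and join the same BH family.
#'
#' @param results NCA result tibble from [nca_study()] (may contain several
#'   groups; families are formed per group). `"Total"` rows are ignored.
#' @param reference Reference glycoform (default `"G0F"`).
#' @param fdr False discovery rate (default 0.05).
#' @param contrasts Optional data frame with columns `a`, `b` naming extra
#'   glycoform-vs-glycoform contrasts.
#' @return Tibble with one row per contrast: `group`, `glycoform`,
#'   `reference`, `n`, `mean_a`, `mean_b`, `mean_diff`, `t`, `df`, `p`,
#'   `alpha_adjusted`, `significant`, `stars`, `degenerate`.
#' @export
compare_glycoforms <- function(results, reference = "G0F", fdr = 0.05,
                               contrasts = NULL) {
  res <- results[results$glycoform != "Total", ]
  out <- lapply(split(res, res$group), function(grp) {
    wide <- tidyr::pivot_wider(grp[c("animal_id", "glycoform", "clearance_ml_day_kg")],
                               names_from = "glycoform",
                               values_from = "clearance_ml_day_kg")
    if (!reference %in% names(wide)) {
      stop("reference glycoform '", reference, "' has no clearance estimates in group ",
           grp$group[1], call. = FALSE)
    }
    pairs <- tibble::tibble(a = setdiff(unique(grp$glycoform), reference),
                            b = reference)
    if (!is.null(contrasts)) {
      pairs <- dplyr::bind_rows(pairs, tibble::as_tibble(contrasts)[c("a", "b")])
    }
    rows <- lapply(seq_len(nrow(pairs)), function(i) {
      ga <- pairs$a[i]; gb <- pairs$b[i]
      if (!ga %in% names(wide) || !gb %in% names(wide)) return(NULL)
      keep <- !is.na(wide[[ga]]) & !is.na(wide[[gb]])
      if (sum(keep) < 2) {
        # not enough paired animals (e.g. lambda_z not estimable): report the
        # contrast as untestable rather than aborting the family
        return(tibble::tibble(group = grp$group[1], glycoform = ga,
                              reference = gb, n = sum(keep),
                              mean_a = NA_real_, mean_b = NA_real_,
                              mean_diff = NA_real_, t = NA_real_,
                              df = NA_real_, p = NA_real_, degenerate = NA))
      }
      a <- wide[[ga]][keep]; b <- wide[[gb]][keep]
      pt <- paired_test(a, b)
      tibble::tibble(group = grp$group[1], glycoform = ga, reference = gb,
                     n = length(a), mean_a = mean(a), mean_b = mean(b),
                     mean_diff = pt$mean_diff, t = pt$t, df = pt$df, p = pt$p,
                     degenerate = pt$degenerate)
    })
    fam <- dplyr::bind_rows(rows)
    adj <- bh_adjust(fam$p, fdr = fdr)
    fam$alpha_adjusted <- adj$alpha_adjusted
    fam$significant <- adj$reject
    fam$stars <- stars_for(fam$p, fam$significant)
    fam
  })
  out <- dplyr::bind_rows(out)
  cols <- c("group", "glycoform", "reference", "n", "mean_a", "mean_b",
            "mean_diff", "t", "df", "p", "alpha_adjusted", "significant",
            "stars", "degenerate")
  tibble::as_tibble(out[cols])
}
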