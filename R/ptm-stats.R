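#' @include AllClasses.R annotations.R
NULL

#' Normalize site counts to a uniform 400-residue length
#'
#' Per-protein: `count * 400 / length`. The proteome-level density of
#' [pooledDensityPer400()] is `sum(counts) * 400 / sum(lengths)` — a pooled
#' normalization over the whole proteome, not the mean of per-protein
#' densities.
#'
#' @param count site (or region) count, vectorized.
#' @param length protein length in residues, vectorized; must be positive.
#' @return sites per 400 residues.
#' @examples
#' densityPer400(4, 800)                      # 2
#' pooledDensityPer400(c(1, 0), c(100, 300))  # 1
#' @export
densityPer400 <- function(count, length) {
  if (any(length <= 0)) stop("length must be positive")
  count * 400 / length
}

#' @rdname densityPer400
#' @param counts,lengths parallel vectors pooled over a proteome.
#' @export
pooledDensityPer400 <- function(counts, lengths) {
  if (sum(lengths) <= 0) stop("total length must be positive")
  sum(counts) * 400 / sum(lengths)
}

#' Bin proteins by site count and average their disorder content
#'
#' Proteins with `count < cap` go to the bin of their exact count; proteins
#' with `count >= cap` pool into the final `">=cap"` bin (the series runs
#' 0, 1, ..., cap-1, >=cap). Each retained bin reports its protein count and
#' the arithmetic mean of its members' disorder content; empty bins are
#' dropped.
#'
#' @param counts integer site counts per protein.
#' @param disorder per-protein disorder fractions, parallel to `counts`.
#' @param cap pooling cap K; default 7.
#' @param parameter optional label stored in `attr(, "parameter")`.
#' @return data.frame `bin_index` (numeric 0..cap; the pooled bin takes
#'   `cap`), `bin_label`, `n_proteins`, `mean_disorder`. Fewer than 3
#'   non-empty bins is flagged with `attr(, "correlation_ok") = FALSE`.
#' @export
binBySiteCount <- function(counts, disorder, cap = 7L,
                           parameter = NA_character_) {
  stopifnot(length(counts) == length(disorder), cap >= 1L)
  idx <- pmin(as.integer(counts), cap)
  levs <- 0:cap
  n <- tabulate(idx + 1L, nbins = cap + 1L)
  means <- vapply(levs, function(k)
    if (n[k + 1L] > 0L) mean(disorder[idx == k]) else NA_real_, numeric(1))
  keep <- n > 0L
  out <- data.frame(
    bin_index = levs[keep],
    bin_label = ifelse(levs[keep] == cap, paste0(">=", cap),
                       as.character(levs[keep])),
    n_proteins = n[keep],
    mean_disorder = means[keep],
    stringsAsFactors = FALSE)
  attr(out, "parameter") <- parameter
  attr(out, "correlation_ok") <- nrow(out) >= 3L
  out
}

#' Pearson correlation of a bin series with one-tailed inference
#'
#' Correlates the numeric bin index (the pooled `">=K"` bin takes the value
#' K) with the per-bin mean disorder content, and reports the one-tailed p
#' value for the observed direction: `t = r * sqrt(n - 2) / sqrt(1 - r^2)`
#' and `p = P(T_{n-2} > |t|)`.
#'
#' @param series a data.frame from [binBySiteCount()], or anything with
#'   numeric columns `bin_index` and `mean_disorder`; alternatively supply
#'   `x` and `y` directly.
#' @param x,y optional raw coordinate vectors overriding `series`.
#' @return list with `r`, `n`, `t`, `p_one_tailed`, `direction`
#'   (`"positive"`/`"negative"`).
#' @examples
#' # r = 0.976 over 8 bins gives a one-tailed p of 1.7e-05
#' rToOneTailedP(0.976, 8)
#' @export
pearsonOneTailed <- function(series = NULL, x = NULL, y = NULL) {
  if (is.null(x)) { x <- series$bin_index; y <- series$mean_disorder }
  n <- length(x)
  if (n < 3L) stop("at least 3 bin points are required")
  if (stats::sd(y) == 0) stop("zero variance in mean disorder; r undefined")
  r <- stats::cor(x, y)
  res <- rToOneTailedP(r, n)
  list(r = r, n = n, t = res[["t"]], p_one_tailed = res[["p"]],
       direction = if (r >= 0) "positive" else "negative")
}

#' One-tailed p from a Pearson coefficient
#'
#' The t transform of a correlation over `n` points with the upper tail of
#' Student's t at `n - 2` degrees of freedom, reported for the observed
#' direction (i.e. at `|t|`).
#'
#' @param r Pearson correlation coefficient(s).
#' @param n number of points (scalar or parallel to `r`).
#' @return named numeric matrix-like vector for scalar input
#'   (`c(t = , p = )`) or a data.frame for vector input.
#' @export
rToOneTailedP <- function(r, n) {
  stopifnot(all(n >= 3), all(abs(r) <= 1))
  t <- abs(r) * sqrt(n - 2) / sqrt(1 - r^2)
  p <- stats::pt(t, df = n - 2, lower.tail = FALSE)
  if (length(r) == 1L && length(n) == 1L) c(t = t, p = p)
  else data.frame(r = r, n = n, t = t, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up FDR adjustment, returned in input order.
#'
#' @param pvals vector of p values in (0, 1].
#' @return adjusted q values, same length and order.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bhFdr <- function(pvals) {
  stopifnot(all(pvals > 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

#' Disordered/ordered PTM density ratio (Rd/o)
#'
#' `Rd/o = (Nd / Ld) / (No / Lo)`: the density of PTM sites in disordered
#' residues relative to their density in ordered residues, pooled over a
#' proteome. A value of 1 means no structural preference; > 1 means the PTM
#' prefers disordered regions.
#'
#' @param sites data.frame of counted sites with columns `protein_id` and
#'   `position` (the anchor residue).
#' @param masks named list of per-residue 0/1 disorder vectors covering
#'   every `protein_id` in `sites`.
#' @return list with `Nd`, `Ld`, `No`, `Lo`, `rdo`. When `No = 0` with
#'   `Nd > 0` the ratio is `Inf`; when `Ld` or `Lo` is 0 it is `NA` (both
#'   signaled with a warning).
#' @export
rdo <- function(sites, masks) {
  lens <- splitResidues(masks)
  Ld <- lens[["Ld"]]; Lo <- lens[["Lo"]]
  Nd <- 0L; No <- 0L
  if (nrow(sites)) {
    if (!all(sites$protein_id %in% names(masks)))
      stop("sites reference proteins without a disorder mask")
    state <- mapply(function(id, pos) masks[[id]][pos],
                    sites$protein_id, sites$position)
    if (anyNA(state)) stop("site position outside its protein's mask")
    Nd <- sum(state == 1L); No <- sum(state == 0L)
  }
  r <- if (Ld == 0 || Lo == 0) {
    warning("degenerate proteome: Ld or Lo is zero; rdo undefined",
            call. = FALSE)
    NA_real_
  } else if (No == 0) {
    if (Nd == 0) NA_real_ else {
      warning("no sites in ordered regions; rdo infinite", call. = FALSE)
      Inf
    }
  } else (Nd / Ld) / (No / Lo)
  list(Nd = Nd, Ld = unname(Ld), No = No, Lo = unname(Lo), rdo = r)
}

#' Pool Rd/o results over species groups
#'
#' Group-level (and total) ratios are computed from the pooled counts
#' `Nd, Ld, No, Lo` across the group's proteomes — not as means of
#' per-species ratios.
#'
#' @param perSpecies named list of [rdo()] results (names = species ids), or
#'   a data.frame with columns `species_id`, `Nd`, `Ld`, `No`, `Lo`.
#' @param grouping named character vector mapping species id to group.
#' @return data.frame `group`, `Nd`, `Ld`, `No`, `Lo`, `rdo`, one row per
#'   group plus a final `"Total"` row pooling every species.
#' @export
groupAggregateRdo <- function(perSpecies, grouping) {
  if (is.data.frame(perSpecies)) d <- perSpecies
  else d <- data.frame(species_id = names(perSpecies),
                       Nd = vapply(perSpecies, `[[`, numeric(1), "Nd"),
                       Ld = vapply(perSpecies, `[[`, numeric(1), "Ld"),
                       No = vapply(perSpecies, `[[`, numeric(1), "No"),
                       Lo = vapply(perSpecies, `[[`, numeric(1), "Lo"),
                       stringsAsFactors = FALSE)
  miss <- setdiff(d$species_id, names(grouping))
  if (length(miss)) stop("no group for species: ", paste(miss, collapse = ", "))
  d$group <- unname(grouping[d$species_id])
  pool <- function(dd) {
    c(Nd = sum(dd$Nd), Ld = sum(dd$Ld), No = sum(dd$No), Lo = sum(dd$Lo))
  }
  rows <- lapply(split(d, d$group), pool)
  rows[["Total"]] <- pool(d)
  out <- do.call(rbind, lapply(names(rows), function(g) {
    v <- rows[[g]]
    data.frame(group = g, Nd = v[["Nd"]], Ld = v[["Ld"]], No = v[["No"]],
               Lo = v[["Lo"]],
               rdo = if (v[["Ld"]] > 0 && v[["Lo"]] > 0 && v[["No"]] > 0)
                 (v[["Nd"]] / v[["Ld"]]) / (v[["No"]] / v[["Lo"]])
               else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
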