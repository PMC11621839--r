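#' Haplotype frequency spectrum
#'
#' An ordered list of haplotype frequencies p1 >= p2 >= ... used by the
#' haplotype-homozygosity sweep statistics. Counts are normalised
#' internally; zero-frequency entries are dropped.
#'
#' @param freqs numeric vector of haplotype frequencies or counts (> 0
#'   entries kept).
#' @param labels optional haplotype labels.
#' @return an object of class \code{haplotype_spectrum}: a data.frame with
#'   columns \code{haplotype}, \code{freq}, sorted by decreasing frequency.
#' @export
haplotype_spectrum <- function(freqs, labels = NULL) {
  if (length(freqs) == 0L) stop("empty haplotype spectrum")
  if (any(freqs < 0)) stop("haplotype frequencies must be nonnegative")
  if (is.null(labels)) labels <- names(freqs)
  if (is.null(labels)) labels <- paste0("h", seq_along(freqs))
  keep <- freqs > 0
  if (!any(keep)) stop("all haplotype frequencies are zero")
  freqs <- freqs[keep]; labels <- labels[keep]
  tot <- sum(freqs)
  is_counts <- any(freqs > 1) || all(abs(freqs - round(freqs)) < 1e-9)
  if (!is_counts && abs(tot - 1) > 1e-9)
    stop("frequencies must sum to 1 (or pass counts)")
  f <- freqs / tot
  ord <- order(f, decreasing = TRUE)
  structure(data.frame(haplotype = labels[ord], freq = unname(f[ord])),
            class = c("haplotype_spectrum", "data.frame"))
}

#' Haplotype homozygosity statistics H1, H2 and H2/H1
#'
#' H1 = sum of squared haplotype frequencies (the haplotype homozygosity);
#' H2 = the same sum excluding the most frequent haplotype. Their ratio
#' H2/H1 separates hard sweeps (one haplotype dominates, ratio near 0) from
#' soft sweeps and neutral variation (ratio closer to 1). The statistics are
#' invariant to haplotype relabelling and to the ordering of ties.
#'
#' @param spectrum a \code{\link{haplotype_spectrum}}, or a numeric vector
#'   of frequencies/counts which is converted first.
#' @return list with \code{H1}, \code{H2} and \code{H2_over_H1}.
#' @examples
#' h_statistics(c(0.5, 0.5))           # H1 0.5, H2 0.25, ratio 0.5
#' h_statistics(c(99, 1))              # counts are fine
#' @export
h_statistics <- function(spectrum) {
  if (!inherits(spectrum, "haplotype_spectrum"))
    spectrum <- haplotype_spectrum(spectrum)
  p <- spectrum$freq
  H1 <- sum(p^2)
  H2 <- H1 - p[1]^2
  list(H1 = H1, H2 = H2, H2_over_H1 = H2 / H1)
}

#' Collapse haplotype labels to a subset of loci
#'
#' Restricts binary haplotype strings to the given locus positions and
#' re-aggregates counts. Useful for computing haplotype statistics on the
#' flanking loci only, excluding the focal site (whose derived allele is the
#' swept novelty itself in genetic and cultural sweep simulations).
#'
#' @param tables a data.frame with a \code{haplotype} column of equal-length
#'   strings and a \code{count} (or \code{freq}) column; other columns are
#'   treated as grouping keys.
#' @param loci integer positions (1-based characters) to keep.
#' @return a data.frame of the same shape with collapsed haplotypes and
#'   summed counts.
#' @export
collapse_haplotypes <- function(tables, loci) {
  stopifnot("haplotype" %in% names(tables))
  val_col <- intersect(c("count", "freq", "count_or_freq"), names(tables))[1]
  if (is.na(val_col)) stop("need a count or freq column")
  sub <- vapply(strsplit(tables$haplotype, ""), function(ch)
    paste(ch[loci], collapse = ""), character(1))
  tables$haplotype <- sub
  keys <- setdiff(names(tables), val_col)
  out <- stats::aggregate(tables[[val_col]], tables[keys], sum)
  names(out)[ncol(out)] <- val_col
  out
}

#' H2/H1 per sweep and per condition
#'
#' Applies \code{\link{h_statistics}} to every (group, sweep) haplotype
#' table and summarises the ratio per condition - the tabular form of a
#' hard / cultural / neutral sweep-signature comparison.
#'
#' @param tables a data.frame with columns \code{group}, \code{haplotype},
#'   and \code{count} (or \code{freq}); an optional \code{sweep_id} column
#'   separates replicate sweeps within a group (a single sweep per group is
#'   assumed otherwise).
#' @return list with \code{per_sweep} (data.frame: group, sweep_id, H1, H2,
#'   H2_over_H1) and \code{means} (data.frame: group, mean_H2_over_H1,
#'   n_sweeps).
#' @export
h_ratio_by_condition <- function(tables) {
  stopifnot(is.data.frame(tables), "group" %in% names(tables),
            "haplotype" %in% names(tables))
  val_col <- intersect(c("count", "freq", "count_or_freq"), names(tables))[1]
  if (is.na(val_col)) stop("need a count or freq column")
  if (!"sweep_id" %in% names(tables)) tables$sweep_id <- 1L
  keys <- unique(tables[c("group", "sweep_id")])
  per <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- tables$group == keys$group[i] & tables$sweep_id == keys$sweep_id[i]
    h <- h_statistics(haplotype_spectrum(tables[[val_col]][sel],
                                         tables$haplotype[sel]))
    data.frame(group = keys$group[i], sweep_id = keys$sweep_id[i],
               H1 = h$H1, H2 = h$H2, H2_over_H1 = h$H2_over_H1)
  }))
  means <- stats::aggregate(H2_over_H1 ~ group, per, mean)
  names(means)[2] <- "mean_H2_over_H1"
  means$n_sweeps <- as.vector(table(per$group)[means$group])
  list(per_sweep = per, means = means)
}
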