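#' Per-gene slice profile
#'
#' One gene's ordered FPKM values along the anteroposterior axis of a single
#' embryo, anterior first, together with a per-slice QC mask (`TRUE` =
#' usable slice).
#'
#' @param gene_id,embryo_id identifiers.
#' @param values numeric FPKM per slice, length >= 5, all finite and >= 0.
#' @param qc_mask logical per slice; defaults to all usable.
#' @return An object of class `slice_profile`.
#' @export
slice_profile <- function(gene_id, embryo_id, values, qc_mask = NULL) {
  values <- as.numeric(values)
  if (length(values) < 5L) stop("a profile needs at least 5 slices")
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("profile values must be finite and >= 0")
  }
  if (is.null(qc_mask)) qc_mask <- rep(TRUE, length(values))
  stopifnot(is.logical(qc_mask), length(qc_mask) == length(values))
  structure(list(gene_id = as.character(gene_id),
                 embryo_id = as.character(embryo_id),
                 values = values, qc_mask = qc_mask),
            class = "slice_profile")
}

#' Impute QC-failed slices from their neighbors
#'
#' Each failed interior slice is replaced by the mean of the nearest usable
#' slice on each side; a failed terminal slice (or a failed run touching an
#' end) copies the nearest usable slice's value.  The returned profile is
#' fully usable.
#'
#' @param profile a [slice_profile()].
#' @return A `slice_profile` with all slices usable.
#' @export
impute_bad_slices <- function(profile) {
  stopifnot(inherits(profile, "slice_profile"))
  ok <- profile$qc_mask
  if (!any(ok)) stop("all slices failed QC; nothing to impute from")
  v <- profile$values
  idx_ok <- which(ok)
  for (i in which(!ok)) {
    left <- idx_ok[idx_ok < i]
    right <- idx_ok[idx_ok > i]
    v[i] <- if (length(left) && length(right)) {
      (v[max(left)] + v[min(right)]) / 2
    } else if (length(left)) {
      v[max(left)]
    } else {
      v[min(right)]
    }
  }
  slice_profile(profile$gene_id, profile$embryo_id, v)
}

#' Max-normalize a slice profile for display
#'
#' Divides by the larger of the profile maximum and a floor (default
#' 10 FPKM), so that weakly expressed genes are not blown up to full
#' intensity.  Used for heatmaps and averaged patterns; EMD computations use
#' mass renormalization instead (see [to_distribution()]).
#'
#' @param values numeric FPKM vector, >= 0.
#' @param floor FPKM floor for the denominator.
#' @return numeric vector in `[0, 1]`.
#' @export
max_normalize <- function(values, floor = 10) {
  if (any(values < 0)) stop("negative expression values")
  values / max(max(values), floor)
}

#' Convert a slice profile into a unit-mass spatial distribution
#'
#' Places a point mass at each slice center `(i - 0.5) / N` on `[0, 1]`,
#' proportional to the slice's value, renormalized to total mass 1.  An
#' all-zero profile is returned with the `all_zero` flag set and must be
#' excluded from EMD comparisons (classify such genes as low-expression
#' instead).
#'
#' @param values numeric FPKM vector, >= 0.
#' @param positions optional atom positions; defaults to slice centers.
#' @return An object of class `spatial_distribution` with fields
#'   `positions`, `masses`, `all_zero`.
#' @export
to_distribution <- function(values, positions = NULL) {
  values <- as.numeric(values)
  if (any(values < 0)) stop("negative expression values")
  n <- length(values)
  if (is.null(positions)) positions <- (seq_len(n) - 0.5) / n
  stopifnot(length(positions) == n, !is.unsorted(positions, strictly = TRUE))
  tot <- sum(values)
  if (tot == 0) {
    return(structure(list(positions = positions, masses = rep(0, n),
                          all_zero = TRUE),
                     class = "spatial_distribution"))
  }
  structure(list(positions = positions, masses = values / tot,
                 all_zero = FALSE),
            class = "spatial_distribution")
}

#' Exact 1-D Earth Mover's Distance between two spatial distributions
#'
#' Computes the Wasserstein-1 distance with ground distance `|x - y|` on
#' `[0, 1]` as the integral of the absolute difference of the two CDFs.
#' The two distributions may have different numbers of atoms (embryos with
#' different slice counts).  The result lies in `[0, 1]`, is symmetric, and
#' is zero iff the distributions are identical.
#'
#' @param a,b `spatial_distribution` objects (see [to_distribution()]).
#' @return numeric EMD value.
#' @export
emd <- function(a, b) {
  stopifnot(inherits(a, "spatial_distribution"),
            inherits(b, "spatial_distribution"))
  if (a$all_zero || b$all_zero) {
    stop("EMD is undefined for an all-zero profile; ",
         "classify the gene as low_expression instead")
  }
  .emd_vec(a$positions, a$masses, b$positions, b$masses)
}

# CDF-integral Wasserstein-1 on raw position/mass vectors (unit masses)
.emd_vec <- function(pos_a, mass_a, pos_b, mass_b) {
  pos <- c(pos_a, pos_b)
  signed <- c(mass_a, -mass_b)
  o <- order(pos)
  pos <- pos[o]
  cdf_diff <- cumsum(signed[o])
  n <- length(pos)
  sum(abs(cdf_diff[-n]) * diff(pos))
}

#' Transportation-problem oracle for the 1-D EMD (testing aid)
#'
#' Solves the underlying transportation problem directly by the
#' north-west-corner rule on position-sorted atoms.  Because the ground cost
#' `|x - y|` on the line satisfies the Monge property, the north-west-corner
#' plan on sorted marginals is already optimal, so no improvement phase is
#' needed.  This is an independent computation path from [emd()]'s
#' CDF-integral and serves as its oracle in the test suite.
#'
#' @param a,b `spatial_distribution` objects; total atom count should stay
#'   small (<= a few hundred).
#' @return numeric EMD value.
#' @export
emd_lp_oracle <- function(a, b) {
  stopifnot(inherits(a, "spatial_distribution"),
            inherits(b, "spatial_distribution"))
  if (abs(sum(a$masses) - 1) > 1e-9 || abs(sum(b$masses) - 1) > 1e-9) {
    stop("infeasible transportation problem: masses must each sum to 1")
  }
  oa <- order(a$positions); ob <- order(b$positions)
  xa <- a$positions[oa]; ma <- a$masses[oa]
  xb <- b$positions[ob]; mb <- b$masses[ob]
  i <- 1L; j <- 1L; cost <- 0
  while (i <= length(xa) && j <= length(xb)) {
    f <- min(ma[i], mb[j])
    cost <- cost + f * abs(xa[i] - xb[j])
    ma[i] <- ma[i] - f
    mb[j] <- mb[j] - f
    if (ma[i] <= 1e-15) i <- i + 1L
    if (j <= length(xb) && mb[j] <= 1e-15) j <- j + 1L
  }
  cost
}

#' EMD of a profile to the uniform distribution over the same slices
#'
#' The basis of the uniform / patterned classification: a flat profile
#' scores 0, a profile concentrated in few slices scores high.
#'
#' @param values numeric FPKM vector (or a [slice_profile()]).
#' @return numeric EMD value.
#' @export
emd_to_uniform <- function(values) {
  if (inherits(values, "slice_profile")) values <- values$values
  d <- to_distribution(values)
  if (d$all_zero) {
    stop("EMD is undefined for an all-zero profile; ",
         "classify the gene as low_expression instead")
  }
  u <- to_distribution(rep(1, length(values)))
  emd(d, u)
}

#' Similarity of slices as a function of their distance apart
#'
#' For each offset `d = 1 .. N-1`, the mean Spearman correlation of
#' genome-wide expression vectors over all slice pairs `(i, i + d)` of one
#' embryo.  In patterned embryos, adjacent slices act as pseudo-replicates:
#' similarity decays with offset.  Offsets with fewer than two defined
#' correlations (e.g. zero-variance slices) are omitted.
#'
#' @param expr genes x slices numeric matrix for one embryo.
#' @return data.frame with columns `offset`, `similarity`, `n_pairs`.
#' @export
adjacent_slice_similarity <- function(expr) {
  expr <- as.matrix(expr)
  n <- ncol(expr)
  if (n < 3L) stop("need at least 3 slices")
  res <- lapply(seq_len(n - 1L), function(d) {
    pairs <- seq_len(n - d)
    cors <- vapply(pairs, function(i) {
      suppressWarnings(cor(expr[, i], expr[, i + d], method = "spearman"))
    }, numeric(1))
    cors <- cors[is.finite(cors)]
    if (length(cors) < 2L) return(NULL)
    data.frame(offset = d, similarity = mean(cors), n_pairs = length(cors))
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(offset = integer(), similarity = numeric(),
                      n_pairs = integer())
  }
  out
}
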