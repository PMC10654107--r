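# Mean-field direct coupling analysis of inter-protein residue covariance.
#
# Model: sequence reweighting at an identity cutoff, pseudocounted single-
# and pair frequencies, couplings from the negative inverse of the
# connected-correlation matrix (one state per column gauged out — the gap
# state), and direct information from the two-site direct distribution with
# compatibility fields fitted by fixed-point iteration.

DCA_ALPHABET <- c(AA_ALPHABET, "-")  # gap is state q, the gauged-out state

#' Pair two alignments by genome
#'
#' Builds the concatenated (paired) alignment used for inter-protein
#' covariance: rows are retained only for genomes present in both
#' alignments, blocks are tracked, and rows are ordered by genome id. If a
#' genome appears more than once in one alignment, the first row is kept
#' with a warning.
#'
#' @param msa_a,msa_b `protein_msa` objects (rows named by protein id).
#' @param genome_of_a,genome_of_b Named character vectors mapping protein
#'   id to genome id.
#' @return A `paired_msa` object (see [generate_paired_msa()]).
#' @export
pair_msa <- function(msa_a, msa_b, genome_of_a, genome_of_b) {
  ga <- unname(genome_of_a[names(msa_a$rows)])
  gb <- unname(genome_of_b[names(msa_b$rows)])
  assert_that(!anyNA(ga) && !anyNA(gb),
              "every alignment row must map to a genome")
  if (anyDuplicated(ga) || anyDuplicated(gb)) {
    warning("duplicate genomes in an alignment; keeping the first row")
  }
  keep_a <- !duplicated(ga)
  keep_b <- !duplicated(gb)
  rows_a <- stats::setNames(msa_a$rows[keep_a], ga[keep_a])
  rows_b <- stats::setNames(msa_b$rows[keep_b], gb[keep_b])
  shared <- sort(intersect(names(rows_a), names(rows_b)))
  if (length(shared) == 0) warning("no shared genomes between alignments")
  mat <- do.call(rbind, lapply(shared, function(g) {
    c(strsplit(rows_a[[g]], "", fixed = TRUE)[[1]],
      strsplit(rows_b[[g]], "", fixed = TRUE)[[1]])
  }))
  if (is.null(mat)) mat <- matrix("", 0, msa_a$n_cols + msa_b$n_cols)
  rownames(mat) <- shared
  structure(list(msa = mat, block_a_cols = seq_len(msa_a$n_cols),
                 block_b_cols = msa_a$n_cols + seq_len(msa_b$n_cols),
                 planted_pairs = NULL, noise = NA_real_),
            class = "paired_msa")
}

#' Mean-field direct coupling analysis of a paired alignment
#'
#' Computes direct information (DI, in nats) between alignment columns:
#' sequences are reweighted (weight `1 / n` where `n` counts rows within
#' `reweight_identity`), frequencies receive a pseudocount of
#' `pseudocount * M_eff`, couplings are the negative inverse of the
#' connected-correlation matrix over `q - 1` states per column (the gap
#' state is gauged out), and each pair's two-site direct distribution gets
#' compatibility fields matched to the single-site marginals by fixed-point
#' (iterative proportional scaling) iteration, converged when the
#' normalized field vectors change by less than 1e-6 (at most 10,000
#' iterations). Columns with more
#' than 50% gaps are excluded. DI is computed for every retained column
#' pair; inter-block pairs are tabulated separately.
#'
#' @param paired A `paired_msa` object with at least 50 rows.
#' @param pseudocount Pseudocount weight in units of M_eff (default 0.5).
#' @param reweight_identity Identity cutoff for sequence reweighting
#'   (default 0.8).
#' @return A `dca_result` object: `di` (symmetric matrix over retained
#'   columns, labeled by original column index), `inter_pairs` tibble
#'   (`col_a`, `col_b` 1-based within each block, `di`), `m_eff`,
#'   `n_rows`, `retained_cols`.
#' @export
mfdca <- function(paired, pseudocount = 0.5, reweight_identity = 0.8) {
  assert_that(inherits(paired, "paired_msa"), "paired must be a paired_msa")
  msa <- paired$msa
  M <- nrow(msa)
  assert_that(M >= 50, "need >= 50 paired rows")
  q <- length(DCA_ALPHABET)

  gap_frac <- colMeans(msa == GAP_CHAR)
  keep <- which(gap_frac <= 0.5)
  L <- length(keep)
  assert_that(L >= 2, "fewer than 2 columns survive the gap filter")
  X <- matrix(match(msa[, keep], DCA_ALPHABET), M, L)
  X[is.na(X)] <- q  # unknown residues treated as the gauged-out state

  # sequence reweighting via one-hot cross products
  onehot <- lapply(seq_len(L), function(j) {
    Ind <- matrix(0, M, q)
    Ind[cbind(seq_len(M), X[, j])] <- 1
    Ind
  })
  matches <- matrix(0, M, M)
  for (j in seq_len(L)) matches <- matches + tcrossprod(onehot[[j]])
  w <- 1 / rowSums(matches / L >= reweight_identity)
  m_eff <- sum(w)
  lambda <- pseudocount * m_eff

  # single-site and pair frequencies (pseudocounted)
  denom <- lambda + m_eff
  fi <- matrix(0, L, q)
  for (j in seq_len(L)) {
    fi[j, ] <- (lambda / q + colSums(onehot[[j]] * w)) / denom
  }
  wonehot <- lapply(onehot, function(o) o * w)
  fij <- function(i, j) {
    (lambda / q^2 + crossprod(wonehot[[i]], onehot[[j]])) / denom
  }

  # connected-correlation matrix over q-1 states per column
  qm <- q - 1
  C <- matrix(0, L * qm, L * qm)
  idx <- function(i) ((i - 1) * qm + 1):(i * qm)
  for (i in seq_len(L)) {
    for (j in i:L) {
      blk <- if (i == j) {
        diag(fi[i, 1:qm]) - tcrossprod(fi[i, 1:qm])
      } else {
        fij(i, j)[1:qm, 1:qm] - tcrossprod(fi[i, 1:qm], fi[j, 1:qm])
      }
      C[idx(i), idx(j)] <- blk
      if (i != j) C[idx(j), idx(i)] <- t(blk)
    }
  }
  invC <- tryCatch(solve(C), error = function(e) {
    warning("connected-correlation matrix is singular; adding ridge 1e-8")
    solve(C + diag(1e-8, nrow(C)))
  })

  pair_di <- function(i, j) {
    W <- matrix(1, q, q)
    W[1:qm, 1:qm] <- exp(-invC[idx(i), idx(j)])
    f1 <- fi[i, ]; f2 <- fi[j, ]
    # compatibility fields by sequential proportional scaling (the mu
    # fixed point of the two-site model); the fixed-point residual — the
    # successive change of the normalized field vectors — is the
    # convergence measure, as in the standard mean-field formulation
    x <- rep(1, q); y <- rep(1, q)
    mu1 <- x / q; mu2 <- y / q
    max_it <- 10000  # near-deterministic couplings converge slowly
    for (it in seq_len(max_it)) {
      x <- f1 / as.vector(W %*% y)
      y <- f2 / as.vector(crossprod(W, x))
      n1 <- x / sum(x); n2 <- y / sum(y)
      eps <- max(abs(n1 - mu1), abs(n2 - mu2))
      mu1 <- n1; mu2 <- n2
      if (eps < 1e-6) break
      if (it == max_it) stop("field iteration did not converge for column pair (",
                             keep[i], ", ", keep[j], ")")
    }
    Pdir <- W * tcrossprod(x, y)
    Pdir <- Pdir / sum(Pdir)
    Pfac <- tcrossprod(f1, f2)
    max(0, sum(Pdir * log(Pdir / Pfac)))
  }

  di <- matrix(0, L, L, dimnames = list(keep, keep))
  for (i in seq_len(L - 1)) for (j in (i + 1):L) {
    di[i, j] <- di[j, i] <- pair_di(i, j)
  }

  in_a <- keep %in% paired$block_a_cols
  in_b <- keep %in% paired$block_b_cols
  rows <- list()
  for (i in which(in_a)) for (j in which(in_b)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      col_a = keep[i], col_b = keep[j] - length(paired$block_a_cols),
      di = di[i, j])
  }
  inter <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(col_a = integer(), col_b = integer(), di = double())
  structure(list(di = di, inter_pairs = inter, m_eff = m_eff,
                 n_rows = M, retained_cols = keep,
                 pseudocount = pseudocount,
                 reweight_identity = reweight_identity),
            class = "dca_result")
}

#' @export
print.dca_result <- function(x, ...) {
  cat("<dca_result> ", x$n_rows, " rows, ", length(x$retained_cols),
      " columns, M_eff = ", round(x$m_eff, 1), ", ",
      nrow(x$inter_pairs), " inter-block pairs\n", sep = "")
  invisible(x)
}

#' Call high inter-protein covariance against controls
#'
#' Takes the top `ceiling(top_fraction * n)` DI values of the analyzed
#' pair and of each control; the verdict is `high` iff the median of the
#' top values exceeds the medians of the top values of both the negative
#' and the positive control. Two-sided Welch t-tests of the top values
#' against each control's top values are reported.
#'
#' @param values Numeric vector of inter-block DI values.
#' @param negative_control,positive_control DI vectors of the control
#'   protein pairs.
#' @param top_fraction Fraction selected (default 0.01, the top-1% rule).
#' @return One-row tibble of class `covariance_call`: `verdict`,
#'   `median_top`, `median_top_negative`, `median_top_positive`,
#'   `p_vs_negative`, `p_vs_positive`, `n_top`.
#' @export
covariance_call <- function(values, negative_control, positive_control,
                            top_fraction = 0.01) {
  assert_that(length(values) > 0 && length(negative_control) > 0 &&
                length(positive_control) > 0, "all lists must be non-empty")
  if (length(values) < 100) {
    warning("fewer than 100 values; top fraction falls back to max(1, ceiling)")
  }
  top_of <- function(x) {
    n <- max(1, ceiling(top_fraction * length(x)))
    sort(x, decreasing = TRUE)[seq_len(n)]
  }
  tv <- top_of(values)
  tn <- top_of(negative_control)
  tp <- top_of(positive_control)
  welch_p <- function(x, y) {
    sx <- if (length(x) > 1) stats::sd(x) else 0
    sy <- if (length(y) > 1) stats::sd(y) else 0
    if (sx < 1e-15 && sy < 1e-15) {
      return(if (abs(mean(x) - mean(y)) < 1e-15) 1 else 0)
    }
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    stats::t.test(x, y, var.equal = FALSE)$p.value
  }
  out <- tibble::tibble(
    verdict = if (stats::median(tv) > stats::median(tn) &&
                  stats::median(tv) > stats::median(tp)) "high" else
                    "not_high",
    median_top = stats::median(tv),
    median_top_negative = stats::median(tn),
    median_top_positive = stats::median(tp),
    p_vs_negative = welch_p(tv, tn),
    p_vs_positive = welch_p(tv, tp),
    n_top = length(tv))
  class(out) <- c("covariance_call", class(out))
  out
}
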