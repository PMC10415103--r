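#' Simplified RNA-RNA duplex energy model
#'
#' A three-parameter stacking-free energy table (arbitrary negative units)
#' with single-nucleotide bulges: GC pairs -3, AU pairs -2, GU wobble -1,
#' +2 penalty per 1-nt bulge. The table is injectable; the analysis only
#' thresholds relative energies, so full nearest-neighbor (Turner)
#' parameters are deliberately out of scope.
#'
#' @param pair_energies Named vector with (symmetric) entries GC, AU, GU,
#'   all negative.
#' @param bulge_penalty Positive penalty per single-nucleotide bulge.
#' @export
energy_model <- function(pair_energies = c(GC = -3, AU = -2, GU = -1),
                         bulge_penalty = 2) {
  stopifnot(all(c("GC", "AU", "GU") %in% names(pair_energies)))
  if (any(pair_energies >= 0)) stop("pair energies must be negative")
  if (bulge_penalty <= 0) stop("bulge penalty must be positive")
  list(pair_energies = pair_energies, bulge_penalty = bulge_penalty,
       max_bulge = 1L)
}

# Symmetric pair-energy lookup (both orientations); unpairable -> Inf.
# N and other ambiguity codes never pair.
.pair_lut <- function(model) {
  pe <- model$pair_energies
  c(GC = pe[["GC"]], CG = pe[["GC"]],
    AU = pe[["AU"]], UA = pe[["AU"]],
    GU = pe[["GU"]], UG = pe[["GU"]])
}

#' Minimum free energy of a local RNA-RNA duplex
#'
#' Local hybridization dynamic program over antiparallel duplexes with no
#' intramolecular structure. With `b' = reverse(seq_b)`,
#' `H(i,j) = e(a_i, b'_j) + min{0, H(i-1,j-1), H(i-2,j-1)+beta, H(i-1,j-2)+beta}`
#' when `(a_i, b'_j)` is pairable, else +Inf; the overall MFE is
#' `min(0, min_ij H(i,j))`. Spans are recovered by traceback with
#' deterministic tie-breaking (prefer more paired bases, then stacking over
#' bulges, then the smaller end coordinates).
#'
#' @param seq_a,seq_b RNA strings (length >= 1).
#' @param model An [energy_model()].
#' @return List with `mfe` (<= 0), `query_span` and `target_span` (0-based
#'   half-open, NULL when no favorable duplex), `n_paired`, and
#'   `paired_fraction` (paired bases over the shorter sequence length).
#' @export
duplex_mfe <- function(seq_a, seq_b, model = energy_model()) {
  if (!nchar(seq_a) || !nchar(seq_b)) stop("empty sequence")
  a <- strsplit(seq_a, "")[[1L]]
  b <- strsplit(seq_b, "")[[1L]]
  brev <- rev(b)
  n <- length(a); m <- length(brev)
  beta <- model$bulge_penalty
  lut <- .pair_lut(model)
  E <- matrix(lut[as.vector(outer(a, brev, paste0))], n, m)
  E[is.na(E)] <- Inf

  # padded by 2 on both axes so predecessors never fall off the matrix
  H <- matrix(Inf, n + 2L, m + 2L)
  L <- matrix(0L, n + 2L, m + 2L)   # paired bases along the optimal path
  P <- matrix(0L, n + 2L, m + 2L)   # 0 start, 1 stack, 2 bulge in a, 3 bulge in b
  jj <- seq_len(m)
  for (i in seq_len(n)) {
    e_row <- E[i, ]
    vA <- H[i + 1L, jj + 1L]              # H(i-1, j-1)
    vB <- H[i, jj + 1L] + beta            # H(i-2, j-1) + beta
    vC <- H[i + 1L, jj] + beta            # H(i-1, j-2) + beta
    best <- pmin(0, vA, vB, vC)
    lA <- ifelse(vA <= best, L[i + 1L, jj + 1L], -1L)
    lB <- ifelse(vB <= best, L[i, jj + 1L], -1L)
    lC <- ifelse(vC <= best, L[i + 1L, jj], -1L)
    l0 <- ifelse(best == 0, 0L, -1L)
    lmax <- pmax(lA, lB, lC, l0)
    opt <- ifelse(lA == lmax, 1L, ifelse(lB == lmax, 2L,
                  ifelse(lC == lmax, 3L, 0L)))
    h <- e_row + best
    usable <- is.finite(h)
    H[i + 2L, jj + 2L] <- ifelse(usable, h, Inf)
    L[i + 2L, jj + 2L] <- ifelse(usable, lmax + 1L, 0L)
    P[i + 2L, jj + 2L] <- ifelse(usable, opt, 0L)
  }

  mfe <- min(0, H[is.finite(H)])
  if (mfe >= 0)
    return(list(mfe = 0, query_span = NULL, target_span = NULL,
                n_paired = 0L, paired_fraction = 0))

  hit <- which(H == mfe, arr.ind = TRUE)
  # prefer more paired bases, then smaller end i, then smaller end j
  lp <- L[hit]
  hit <- hit[order(-lp, hit[, 1L], hit[, 2L]), , drop = FALSE]
  ci <- hit[1L, 1L]; cj <- hit[1L, 2L]
  pi <- integer(0); pj <- integer(0)
  repeat {
    pi <- c(pi, ci - 2L); pj <- c(pj, cj - 2L)
    step <- P[ci, cj]
    if (step == 0L) break
    if (step == 1L) { ci <- ci - 1L; cj <- cj - 1L }
    else if (step == 2L) { ci <- ci - 2L; cj <- cj - 1L }
    else { ci <- ci - 1L; cj <- cj - 2L }
  }
  # map reversed-b columns back to original b coordinates (0-based)
  bpos <- m - pj
  list(mfe = mfe,
       query_span = c(min(pi) - 1L, max(pi)),
       target_span = c(min(bpos), max(bpos) + 1L),
       n_paired = length(pi),
       paired_fraction = length(pi) / min(n, m))
}
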