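#' QNA atom values
#'
#' Per-atom Quantitative-Neighbourhoods-of-Atoms values. Each atom k
#' carries `A_k = (IP_k + EA_k)/2` (eV) and `B_k = (IP_k - EA_k)^(-1/2)`;
#' the whole-molecule influence enters through `E = exp(-C/2)`, the matrix
#' exponential of minus one half of the 0/1 connectivity matrix C:
#' `P = B * (E B)` and `Q = B * (E (B*A))` (elementwise products with B).
#' The matrix exponential propagates through-bond influence with a weight
#' decaying in bond distance, so P and Q describe each atom while
#' depending on the topology of the molecule as a whole.
#'
#' @param mol An `ao_molecule`.
#' @param props Element property table (see [element_properties()]).
#' @param exponential `"matrix"` for the matrix exponential (default) or
#'   `"elementwise"` for an entry-wise exponential of -C/2.
#' @return List of class `ao_qna` with numeric vectors `A`, `B`, `P`, `Q`
#'   (one entry per atom).
#' @export
#' @examples
#' q <- compute_qna(read_smiles("C", "methane"))
#' length(q$P) # 5 atoms
compute_qna <- function(mol, props = element_properties(),
                        exponential = c("matrix", "elementwise")) {
  exponential <- match.arg(exponential)
  el <- mol$atoms$element
  unknown <- setdiff(unique(el), rownames(props))
  if (length(unknown) > 0) stop("element(s) missing from property table: ",
                                paste(unknown, collapse = ", "))
  ip <- props[el, "IP"]
  ea <- props[el, "EA"]
  if (any(ip <= ea)) stop("degenerate element: IP <= EA for ",
                          paste(unique(el[ip <= ea]), collapse = ", "))
  A <- (ip + ea) / 2
  B <- (ip - ea)^(-1 / 2)
  C <- mol$connectivity
  E <- if (exponential == "matrix") {
    as.matrix(Matrix::expm(-0.5 * C))
  } else {
    exp(-0.5 * C)
  }
  P <- as.numeric(B * (E %*% B))
  Q <- as.numeric(B * (E %*% (B * A)))
  structure(list(A = A, B = B, P = P, Q = Q), class = "ao_qna")
}

# Chebyshev polynomials of the first kind T_0..T_deg evaluated at x
# (three-term recurrence); returns length(x) x (deg+1) matrix
chebyshev_t <- function(x, deg) {
  out <- matrix(0, length(x), deg + 1)
  out[, 1] <- 1
  if (deg >= 1) out[, 2] <- x
  if (deg >= 2) {
    for (k in 3:(deg + 1)) out[, k] <- 2 * x * out[, k - 1] - out[, k - 2]
  }
  out
}

#' Robust squashing scales for QNA values
#'
#' The P and Q values are unbounded; before entering the Chebyshev
#' features they are mapped into (-1, 1) by `x -> (2/pi) atan(x/s)`. The
#' scale `s` is the median absolute P (resp. Q) over all atoms of the
#' training set, fixed at fit time.
#'
#' @param qnas List of `ao_qna` objects (the training set).
#' @return List with scales `s_p` and `s_q`.
#' @export
qna_scale_params <- function(qnas) {
  all_p <- unlist(lapply(qnas, `[[`, "P"))
  all_q <- unlist(lapply(qnas, `[[`, "Q"))
  s_p <- stats::median(abs(all_p))
  s_q <- stats::median(abs(all_q))
  list(s_p = if (s_p > 0) s_p else 1, s_q = if (s_q > 0) s_q else 1)
}

#' Chebyshev polynomial features from QNA values
#'
#' Squashes P and Q into (-1, 1) via `(2/pi) atan(x/s)` and returns the
#' per-molecule means of the two-dimensional Chebyshev products
#' `T_m(P') T_n(Q')` for all degrees `0 <= m + n <= max_degree`. Since
#' |T_k| <= 1 on [-1, 1] and averaging preserves the bound, every feature
#' lies in [-1, 1].
#'
#' @param qna An `ao_qna` object.
#' @param max_degree Maximum total degree m+n (default 4, 15 features).
#' @param s_p,s_q Squashing scales (training-set medians; see
#'   [qna_scale_params()]).
#' @return Named numeric vector (`cheb_m_n`) with a `kinds` attribute of
#'   `"qna_chebyshev"`.
#' @export
chebyshev_features <- function(qna, max_degree = 4L, s_p = 1, s_q = 1) {
  stopifnot(max_degree >= 0)
  ph <- (2 / pi) * atan(qna$P / s_p)
  qh <- (2 / pi) * atan(qna$Q / s_q)
  tp <- chebyshev_t(ph, max_degree)
  tq <- chebyshev_t(qh, max_degree)
  vals <- c()
  nms <- c()
  for (m in 0:max_degree) {
    for (n in 0:(max_degree - m)) {
      vals <- c(vals, mean(tp[, m + 1] * tq[, n + 1]))
      nms <- c(nms, paste0("cheb_", m, "_", n))
    }
  }
  names(vals) <- nms
  attr(vals, "kinds") <- rep("qna_chebyshev", length(vals))
  vals
}
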