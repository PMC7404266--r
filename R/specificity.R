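#' Per-tissue mean expression profiles
#'
#' Averages TPM over the samples of each tissue. Tissue order is fixed as the
#' order of first appearance in the sample annotation and recorded in the
#' column order of the result.
#'
#' @param x A `TPMExperiment`.
#' @param ... Unused.
#' @return A gene x tissue numeric matrix of mean TPM.
#' @rdname tissueMeans
#' @export
setMethod("tissueMeans", "TPMExperiment", function(x, ...) {
  tt <- as.character(colData(x)$tissue)
  levels <- unique(tt)
  counts <- table(factor(tt, levels = levels))
  if (any(counts == 0L))
    stop("tissue(s) with zero samples: ",
         paste(names(counts)[counts == 0L], collapse = ", "))
  m <- vapply(levels, function(lv)
    rowMeans(tpm(x)[, tt == lv, drop = FALSE]), numeric(nrow(x)))
  if (nrow(x) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(rownames(x), levels))
  m
})

#' Tau tissue-specificity statistic
#'
#' For a profile of per-tissue mean expression `x` of length `n` with
#' `max(x) > 0`, Tau is
#' \deqn{\tau = \frac{\sum_{i=1}^{n} (1 - \hat x_i)}{n - 1}, \qquad
#'       \hat x_i = \frac{x_i}{\max_{1 \le j \le n} x_j}}
#' Tau ranges from 0 (expressed ubiquitously: a uniform profile) to 1
#' (expressed in a single tissue) and is invariant to rescaling the profile.
#'
#' @param x Non-negative numeric vector of per-tissue means (length >= 2) or
#'   a gene x tissue matrix (Tau is computed per row).
#' @return A numeric scalar, or a named numeric vector for matrix input.
#' @examples
#' computeTau(c(10, 5, 0, 0, 0))  # 0.875
#' @export
computeTau <- function(x) {
  if (is.matrix(x)) return(apply(x, 1L, computeTau))
  if (length(x) < 2L) stop("Tau needs at least two tissues")
  if (any(is.na(x)) || any(x < 0)) stop("profile must be non-negative and complete")
  mx <- max(x)
  if (mx == 0) stop("all-zero profile: Tau normalization undefined")
  sum(1 - x / mx) / (length(x) - 1L)
}

#' Call tissue-specific genes from Tau
#'
#' A gene is called tissue-specific (TSG) when its Tau is at or above the
#' threshold (default 0.8, boundary inclusive); it is assigned to the tissue
#' with the highest mean expression. An exact tie on the maximum sets
#' `tie_flag` and assigns the first tied tissue in the fixed tissue order.
#' Profiles should be pre-filtered to genes with maximum TPM >= 1 (see
#' [filterExpressed()]); all-zero profiles yield `NA` Tau with a warning.
#'
#' @param profiles Gene x tissue matrix of per-tissue mean TPM (from
#'   [tissueMeans()]).
#' @param tau_threshold TSG call threshold on Tau (default 0.8).
#' @return A `data.frame`: gene_id, tau, assigned_tissue, is_tsg, tie_flag,
#'   followed by the per-tissue mean columns.
#' @export
callTSGs <- function(profiles, tau_threshold = 0.8) {
  stopifnot(is.matrix(profiles), ncol(profiles) >= 2L)
  if (is.null(colnames(profiles)) || is.null(rownames(profiles)))
    stop("profiles must carry gene rownames and tissue colnames")
  n <- nrow(profiles)
  tau <- rep(NA_real_, n)
  assigned <- rep(NA_character_, n)
  tie <- logical(n)
  zero <- apply(profiles, 1L, max) == 0
  if (any(zero))
    warning(sum(zero), " all-zero profile(s): Tau reported as NA")
  for (i in which(!zero)) {
    xi <- profiles[i, ]
    tau[i] <- computeTau(xi)
    hits <- which(xi == max(xi))
    assigned[i] <- colnames(profiles)[hits[1L]]
    tie[i] <- length(hits) > 1L
  }
  is_tsg <- !is.na(tau) & tau >= tau_threshold
  assigned[!is_tsg] <- NA_character_
  out <- data.frame(gene_id = rownames(profiles), tau = tau,
                    assigned_tissue = assigned, is_tsg = is_tsg,
                    tie_flag = tie, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(profiles))
}
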