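#' Summary statistics of the learning-disabilities study
#'
#' A classic three-group study (Fleiss, 1986, The Design and Analysis of
#' Clinical Experiments, Section 7.2) compared three methods of treating
#' the learning disabilities of children with respiratory diseases.  The
#' response is the number of correct answers on a 15-question test and the
#' single covariate the score on a similar 7-question pretest.  Only the
#' summary statistics of the ANCOVA are available: adjusted group means
#' {5.7408, 8.5512, 7.8950}, group sizes {19, 20, 20}, slope estimate
#' 1.2946, error variance estimate 3.2728, and covariate disparity
#' statistic Q = 0.2131.
#'
#' With the default contrast `{-1, 1/2, 1/2}` (first treatment against the
#' average of the other two) the contrast of adjusted means is
#' `psi_hat = 2.4823` and the variance factor
#' `V = sum(c^2/N) + Q/(NT - G) = 0.081437`.
#'
#' @param contrast contrast coefficients (default `c(-1, 0.5, 0.5)`).
#' @return a `contrast_estimate` built from the summary statistics (the
#'   quantities requiring raw data are `NA`), with the study constants
#'   attached as attribute `"study"`.
#' @examples
#' est <- fleiss_learning_example()
#' contrast_cis(est, alpha = 0.10)
#' @export
fleiss_learning_example <- function(contrast = c(-1, 0.5, 0.5)) {
  adj_means <- c(5.7408, 8.5512, 7.8950)
  Ni <- c(19L, 20L, 20L)
  Q <- 0.2131
  sigma_sq <- 3.2728
  G <- 3L; P <- 1L
  NT <- sum(Ni)
  validate_contrast(contrast, G)
  psi_hat <- sum(contrast * adj_means)
  a <- sum(contrast^2 / Ni)
  V <- a + Q / (NT - G)
  est <- summary_estimate(psi_hat, sigma_sq, NT - G - P, V)
  est$a <- a
  est$Q <- Q
  est$Ni <- Ni
  est$contrast <- contrast
  attr(est, "study") <- list(adj_means = adj_means, Ni = Ni, beta = 1.2946,
                             sigma_sq = sigma_sq, Q = Q, G = G, P = P)
  est
}
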