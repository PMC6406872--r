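#' Rank-based annotation term score in one dimension
#'
#' Measures where a term's member proteins sit in the distribution of one
#' log-abundance dimension. Values are rank-transformed (average ranks for
#' ties) and the mean member rank is rescaled so that a term occupying the
#' n_t largest values scores exactly +1 and one occupying the n_t smallest
#' scores exactly -1:
#' \deqn{s = 2 \, \frac{\bar R_{members} - (n + 1)/2}{n - n_t}}
#' Being rank-based, the score is invariant under any strictly monotone
#' transform of the values.
#'
#' @param values Numeric vector over all n proteins.
#' @param members Integer or logical index of term members; must be a proper
#'   non-empty subset.
#' @return Score in [-1, 1].
#' @export
term_score <- function(values, members) {
  n <- length(values)
  if (is.logical(members)) members <- which(members)
  n_t <- length(members)
  if (n_t == 0L || n_t >= n) stop("term members must be a proper non-empty subset")
  r <- rank(values, ties.method = "average")
  2 * (mean(r[members]) - (n + 1) / 2) / (n - n_t)
}

#' Two-dimensional term test (Hotelling T-squared on ranks)
#'
#' Tests whether a term's members are jointly shifted in two log-abundance
#' dimensions. Both dimensions are rank-transformed; the member and
#' non-member rank vectors are compared with a two-sample Hotelling
#' T-squared statistic using the pooled covariance, referred to a chi-square
#' with 2 degrees of freedom (an omnibus test: a shift in either dimension
#' alone is detected).
#'
#' @param x,y Numeric vectors over all n proteins (two dimensions).
#' @param members Index or logical vector of term members.
#' @return p-value; 1 (with a warning) when the pooled covariance is
#'   singular.
#' @export
term_test_2d <- function(x, y, members) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (is.logical(members)) members <- which(members)
  n1 <- length(members)
  n2 <- n - n1
  if (n1 < 2L || n2 < 2L) stop("need at least two members and two non-members")
  rmat <- cbind(rank(x, ties.method = "average"),
                rank(y, ties.method = "average"))
  m1 <- colMeans(rmat[members, , drop = FALSE])
  m2 <- colMeans(rmat[-members, , drop = FALSE])
  s1 <- stats::cov(rmat[members, , drop = FALSE])
  s2 <- stats::cov(rmat[-members, , drop = FALSE])
  sp <- ((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2)
  d <- m1 - m2
  sp_inv <- tryCatch(solve(sp), error = function(e) NULL)
  if (is.null(sp_inv)) {
    warning("singular pooled covariance; p-value set to 1")
    return(1)
  }
  t2 <- (n1 * n2 / (n1 + n2)) * drop(t(d) %*% sp_inv %*% d)
  stats::pchisq(t2, df = 2L, lower.tail = FALSE)
}

#' Two-dimensional annotation enrichment
#'
#' For every annotation term with enough members, computes the rank-based
#' scores in both dimensions ([term_score()]) and the joint Hotelling
#' T-squared p-value ([term_test_2d()]), then adjusts p-values across terms
#' by Benjamini-Hochberg. The typical use compares two log copy-number
#' ratios, e.g. HepaRG vs PHH on x and HepG2 vs PHH on y: a liver-function
#' term in the lower-left quadrant is depleted in both cell lines relative
#' to primary hepatocytes.
#'
#' @param x,y Numeric vectors over all proteins (two log-abundance
#'   dimensions).
#' @param annotations Named list: term -> integer indices (or character
#'   accessions resolved against `accessions`).
#' @param accessions Optional accession vector for resolving character
#'   memberships.
#' @param min_members Minimum term size, default 10.
#' @param fdr_threshold Benjamini-Hochberg threshold used for the
#'   `enriched` flag, default 0.02.
#' @return Data frame per retained term: `term`, `n_members`, `score_x`,
#'   `score_y`, `p`, `bh_fdr`, `enriched`.
#' @export
annotation_enrichment_2d <- function(x, y, annotations, accessions = NULL,
                                     min_members = 10L, fdr_threshold = 0.02) {
  stopifnot(length(x) == length(y), is.list(annotations))
  idx_list <- lapply(annotations, function(m) {
    if (is.character(m)) {
      if (is.null(accessions)) stop("character memberships need 'accessions'")
      m <- match(m, accessions)
      m <- m[!is.na(m)]
    }
    unique(m)
  })
  sizes <- lengths(idx_list)
  keep <- sizes >= min_members & sizes < length(x)
  idx_list <- idx_list[keep]
  if (length(idx_list) == 0L) {
    return(data.frame(term = character(), n_members = integer(),
                      score_x = numeric(), score_y = numeric(),
                      p = numeric(), bh_fdr = numeric(),
                      enriched = logical()))
  }
  score_x <- vapply(idx_list, function(m) term_score(x, m), 0)
  score_y <- vapply(idx_list, function(m) term_score(y, m), 0)
  p <- vapply(idx_list, function(m) term_test_2d(x, y, m), 0)
  bh <- stats::p.adjust(p, method = "BH")
  data.frame(
    term = names(idx_list),
    n_members = lengths(idx_list),
    score_x = score_x,
    score_y = score_y,
    p = p,
    bh_fdr = bh,
    enriched = bh < fdr_threshold,
    row.names = NULL
  )
}
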