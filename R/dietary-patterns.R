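#' Build the participant-by-food-group intake matrix
#'
#' Food weights are summed per group and recorded day, then averaged over
#' the participant's recorded days (g/day); groups never consumed are 0,
#' not missing.  The two codebook groups flagged `pca_excluded` ("other",
#' "supplements") are dropped, leaving 25 columns in codebook order.
#'
#' @param entries Diary entries of retained participants.
#' @param participants Participant tibble (defines row order).
#' @param codebook Food-group codebook.
#' @return A list of class `foodgroup_matrix`: `x` (numeric matrix,
#'   participants x groups, rownames = ids), `transform` ("raw" or "log").
#' @export
build_foodgroup_matrix <- function(entries, participants,
                                   codebook = food_group_codebook()) {
  unknown <- setdiff(unique(entries$food_group), codebook$code)
  if (length(unknown)) {
    stop("unknown food-group code(s): ", paste(unknown, collapse = ", "))
  }
  groups <- codebook$code[!codebook$pca_excluded]
  n_days <- entries |>
    dplyr::distinct(.data$participant_id, .data$day) |>
    dplyr::count(.data$participant_id, name = "n_days")
  gday <- entries |>
    dplyr::filter(.data$food_group %in% groups) |>
    dplyr::group_by(.data$participant_id, .data$food_group) |>
    dplyr::summarise(grams = sum(.data$weight), .groups = "drop") |>
    dplyr::left_join(n_days, by = "participant_id") |>
    dplyr::mutate(g_per_day = .data$grams / .data$n_days)
  x <- matrix(0, nrow = nrow(participants), ncol = length(groups),
              dimnames = list(participants$id, groups))
  x[cbind(match(gday$participant_id, participants$id),
          match(gday$food_group, groups))] <- gday$g_per_day
  structure(list(x = x, transform = "raw"), class = "foodgroup_matrix")
}

#' Log-transform a food-group matrix
#'
#' Applies x -> log(x + offset) elementwise.  The default offset of 1 g
#' keeps structural zeros (groups never consumed, e.g. legumes or nuts for
#' most participants) at exactly 0 after transformation.  Applying the
#' transform twice is an error.
#'
#' @param fgm A `foodgroup_matrix` in raw state.
#' @param offset Gram offset added before the log, default 1.
#' @return The matrix object with `transform = "log"`.
#' @export
log_transform <- function(fgm, offset = 1) {
  stopifnot(inherits(fgm, "foodgroup_matrix"))
  if (fgm$transform != "raw") stop("matrix is already log-transformed")
  fgm$x <- log(fgm$x + offset)
  fgm$transform <- "log"
  fgm$offset <- offset
  fgm
}

#' Principal-component dietary patterns with varimax rotation
#'
#' Columns are standardised to zero mean and unit variance (correlation
#' PCA; gram scales differ by orders of magnitude across groups, so
#' covariance PCA would be dominated by beverages).  Components with a
#' pre-rotation eigenvalue above `retain_graphical` are varimax-rotated
#' (Kaiser row normalisation); components above `retain_analysis` form the
#' subset used for further analysis.  Each rotated component's
#' largest-|loading| entry is forced positive so results do not depend on
#' the linear-algebra backend's sign choices.
#'
#' @param fgm A log-state `foodgroup_matrix` (one sex stratum; run per sex,
#'   never sharing scaling parameters across strata).
#' @param retain_graphical Eigenvalue threshold for extraction/rotation,
#'   default 1.0.
#' @param retain_analysis Eigenvalue threshold for downstream use, default
#'   1.5.
#' @param standardise Standardise columns to unit variance, default `TRUE`.
#' @param rotate Apply varimax, default `TRUE`.
#' @return A list of class `dietary_patterns`: `loadings` (groups x
#'   retained components, post-rotation), `eigenvalues` (all components,
#'   pre-rotation), `pct_variance` (per rotated component, post-rotation),
#'   `scores` (participants x retained components, unit variance),
#'   `retained_graphical`, `retained_analysis` (component indices),
#'   `dropped_columns`.
#' @export
pca_varimax <- function(fgm, retain_graphical = 1.0, retain_analysis = 1.5,
                        standardise = TRUE, rotate = TRUE) {
  stopifnot(inherits(fgm, "foodgroup_matrix"))
  if (fgm$transform != "log") stop("log_transform() the matrix first")
  x <- fgm$x
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    warning("dropping zero-variance column(s): ",
            paste(dropped, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  z <- scale(x, center = TRUE, scale = standardise)
  p <- ncol(z)
  cm <- stats::cor(z)
  eig <- eigen(cm, symmetric = TRUE)
  eigenvalues <- eig$values
  keep <- which(eigenvalues > retain_graphical)
  if (!length(keep)) stop("no component exceeds the graphical threshold")
  # component loadings = eigenvectors scaled to component SD
  load_raw <- eig$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eigenvalues[keep]), length(keep))
  rownames(load_raw) <- colnames(z)
  if (rotate && length(keep) > 1) {
    rot <- stats::varimax(load_raw, normalize = TRUE, eps = 1e-8)
    loadings <- unclass(rot$loadings)
    rotmat <- rot$rotmat
  } else {
    loadings <- load_raw
    rotmat <- diag(ncol(load_raw))
  }
  # deterministic sign: largest |loading| per component positive
  signs <- vapply(seq_len(ncol(loadings)), function(j) {
    s <- sign(loadings[which.max(abs(loadings[, j])), j])
    if (s == 0) 1 else s
  }, numeric(1))
  loadings <- sweep(loadings, 2, signs, "*")
  # order rotated components by explained variance (rotation mixes the
  # original eigenvalue order)
  ord <- order(colSums(loadings^2), decreasing = TRUE)
  loadings <- loadings[, ord, drop = FALSE]
  # component scores: standardised principal scores carried through the
  # orthogonal rotation (no correlation-matrix inverse needed, so rank-
  # deficient strata with n < p still score)
  scores_std <- z %*% eig$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(eigenvalues[keep]), length(keep))
  scores <- scores_std %*% rotmat
  scores <- sweep(scores, 2, signs, "*")[, ord, drop = FALSE]
  scores <- sweep(scores, 2, apply(scores, 2, stats::sd), "/")
  colnames(loadings) <- colnames(scores) <-
    paste0("DP", seq_along(keep))
  rownames(scores) <- rownames(x)
  structure(list(
    loadings = loadings,
    eigenvalues = eigenvalues,
    pct_variance = 100 * colSums(loadings^2) / p,
    scores = scores,
    retained_graphical = keep,
    retained_analysis = which(eigenvalues > retain_analysis),
    dropped_columns = dropped
  ), class = "dietary_patterns")
}

#' Tertiles of adherence to a dietary pattern
#'
#' Splits scores into sample tertiles (labels 1 = lowest adherence,
#' 3 = highest).  The quantile convention assigns the first
#' `ceiling(n/3)` ranked observations to tertile 1 when n is not divisible
#' by 3 (so n = 10 gives sizes 4/3/3); ties are broken by stable input
#' order.  All-equal scores degenerate to a single tertile 1 with a
#' warning.
#'
#' @param scores Numeric vector of pattern scores (one sex stratum).
#' @return Integer vector of tertile labels in 1..3.
#' @export
adherence_tertiles <- function(scores) {
  n <- length(scores)
  if (n < 3) stop("need at least 3 observations for tertiles")
  if (length(unique(scores)) == 1) {
    warning("all scores equal; assigning every observation to tertile 1")
    return(rep(1L, n))
  }
  rk <- rank(scores, ties.method = "first")
  sizes <- c(ceiling(n / 3), round(n / 3))
  sizes <- c(sizes, n - sum(sizes))
  cut_points <- cumsum(sizes)
  findInterval(rk, c(0, cut_points), left.open = TRUE)
}

#' Tucker congruence between two loading matrices
#'
#' Matches columns of `est` to columns of `truth` over all permutations and
#' sign flips and returns the congruence coefficient
#' phi = sum(xy) / sqrt(sum(x^2) sum(y^2)) per matched pair, maximising the
#' minimum congruence.  Used to check that rotated patterns recover a
#' planted loading structure up to sign and order.
#'
#' @param est,truth Numeric matrices with the same dimensions (groups x
#'   factors).
#' @return A list: `congruence` (per truth column), `permutation`, `signs`.
#' @export
factor_congruence <- function(est, truth) {
  stopifnot(ncol(est) == ncol(truth), nrow(est) == nrow(truth))
  k <- ncol(truth)
  phi <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  phimat <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    phimat[i, j] <- phi(est[, i], truth[, j])
  }
  perms <- permute_indices(k)
  best <- NULL
  best_min <- -Inf
  for (p in perms) {
    vals <- abs(phimat[cbind(p, seq_len(k))])
    if (min(vals) > best_min) {
      best_min <- min(vals)
      best <- list(congruence = vals, permutation = p,
                   signs = sign(phimat[cbind(p, seq_len(k))]))
    }
  }
  best
}

permute_indices <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (rest in permute_indices(k - 1L)) {
      v <- seq_len(k)[-i]
      out[[length(out) + 1L]] <- c(i, v[rest])
    }
  }
  out
}
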