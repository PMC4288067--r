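# Ranked relation sets and fold-enrichment crossvalidation against an
# external reference set.

#' Ranked relation set
#'
#' Normalizes a table of weighted unordered concept pairs: endpoints stored
#' sorted within each row, duplicates rejected, rows ordered by weight
#' descending with lexicographic tie-break. The deterministic order matters
#' because fold enrichment cuts the list at a rank.
#'
#' @param pairs A data frame with columns `id_a`, `id_b` and `weight`
#'   (positive).
#' @return A tibble of class `ranked_relations`.
#' @export
ranked_relations <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  if (!all(c("id_a", "id_b", "weight") %in% names(pairs))) {
    rlang::abort("`pairs` needs columns `id_a`, `id_b`, `weight`.")
  }
  if (any(pairs$id_a == pairs$id_b)) {
    rlang::abort("relation endpoints must be distinct")
  }
  if (any(pairs$weight <= 0)) {
    rlang::abort("weights must be positive")
  }
  lo <- pmin(pairs$id_a, pairs$id_b)
  hi <- pmax(pairs$id_a, pairs$id_b)
  pairs$id_a <- lo
  pairs$id_b <- hi
  if (anyDuplicated(paste(lo, hi, sep = "\r"))) {
    rlang::abort("duplicate relation pair")
  }
  pairs <- dplyr::arrange(
    pairs, dplyr::desc(.data$weight), .data$id_a, .data$id_b
  )
  class(pairs) <- c("ranked_relations", class(tibble::tibble()))
  pairs
}

#' Unordered reference relation set
#'
#' @param pairs A data frame with columns `id_a`, `id_b`; endpoints are
#'   stored sorted and duplicates collapsed.
#' @return A tibble of class `relation_set`.
#' @export
relation_set <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  if (!all(c("id_a", "id_b") %in% names(pairs))) {
    rlang::abort("`pairs` needs columns `id_a` and `id_b`.")
  }
  if (any(pairs$id_a == pairs$id_b)) {
    rlang::abort("relation endpoints must be distinct")
  }
  lo <- pmin(pairs$id_a, pairs$id_b)
  hi <- pmax(pairs$id_a, pairs$id_b)
  out <- dplyr::distinct(tibble::tibble(id_a = lo, id_b = hi))
  class(out) <- c("relation_set", class(tibble::tibble()))
  out
}

pair_key <- function(df) paste(df$id_a, df$id_b, sep = "\r")

#' Intersection of a reference set with a ranked set
#'
#' Returns the reference pairs that also appear (as unordered pairs) in the
#' ranked set — the pool against which fold enrichment is normalized.
#'
#' @param t A [ranked_relations()] table (or coercible data frame).
#' @param s A [relation_set()] (or coercible data frame).
#' @return A `relation_set` of the common pairs.
#' @export
intersect_relations <- function(t, s) {
  t <- as_ranked(t)
  s <- as_relation_set(s)
  keep <- pair_key(s) %in% pair_key(t)
  relation_set(s[keep, , drop = FALSE])
}

as_ranked <- function(t) {
  if (inherits(t, "ranked_relations")) t else ranked_relations(t)
}

as_relation_set <- function(s) {
  if (inherits(s, "relation_set")) s else relation_set(s)
}

#' Fold enrichment of a ranked relation set at a rank percentage
#'
#' With `S' = S` \eqn{\cap} `T`, the fold enrichment at percentage `alpha`
#' is
#' \deqn{f(\alpha) = \frac{|S'(\alpha)| / |S'|}{|T(\alpha)| / |T|}}
#' where `T(alpha)` is the top `alpha` percent of the ranked list (cutoff
#' `m = round(alpha * |T| / 100)`, half away from zero, never below 1) and
#' `S'(alpha)` the members of `S` among them. Values near 1 are what a
#' random ranking gives; values well above 1 mean the reference pairs
#' concentrate at the top of the ranking.
#'
#' @param t A [ranked_relations()] table.
#' @param s A [relation_set()] of externally confirmed pairs.
#' @param alpha Percentage in `(0, 100]`.
#' @return The fold enrichment (non-negative number); errors when
#'   `S` \eqn{\cap} `T` is empty (the measure is undefined).
#' @export
fold_enrichment <- function(t, s, alpha) {
  t <- as_ranked(t)
  s <- as_relation_set(s)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 100) {
    rlang::abort("`alpha` must be a percentage in (0, 100]")
  }
  s_prime <- intersect_relations(t, s)
  if (nrow(s_prime) == 0) {
    rlang::abort("S and T share no pair; fold enrichment is undefined")
  }
  n_t <- nrow(t)
  m <- max(1L, round_half_up(alpha * n_t / 100))
  top_keys <- pair_key(t)[seq_len(m)]
  hits <- sum(pair_key(s_prime) %in% top_keys)
  (hits / nrow(s_prime)) / (m / n_t)
}

#' Fold-enrichment curve over a grid of percentages
#'
#' @inheritParams fold_enrichment
#' @param alpha_grid Percentages in `(0, 100]`, e.g. `seq(10, 100, 10)`.
#' @return A tibble of class `enrichment_curve` with columns `alpha` and
#'   `f`, carrying `s_prime_size`, `n_t`, `n_s`, `max_f` and `argmax_alpha`
#'   (first grid point attaining the maximum) as attributes; see
#'   [glance.enrichment_curve()].
#' @export
enrichment_curve <- function(t, s, alpha_grid = seq(10, 100, by = 10)) {
  t <- as_ranked(t)
  s <- as_relation_set(s)
  if (length(alpha_grid) == 0) {
    rlang::abort("`alpha_grid` must be non-empty")
  }
  f <- vapply(alpha_grid, function(a) fold_enrichment(t, s, a), numeric(1))
  out <- tibble::tibble(alpha = as.numeric(alpha_grid), f = f)
  attr(out, "s_prime_size") <- nrow(intersect_relations(t, s))
  attr(out, "n_t") <- nrow(t)
  attr(out, "n_s") <- nrow(s)
  attr(out, "max_f") <- max(f)
  attr(out, "argmax_alpha") <- out$alpha[which.max(f)]
  class(out) <- c("enrichment_curve", class(tibble::tibble()))
  out
}

#' @export
tidy.enrichment_curve <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, f = x$f)
}

#' Summary of an enrichment curve
#'
#' @param x An [enrichment_curve()].
#' @param ... Unused.
#' @return One-row tibble: `s_prime_size`, `n_t`, `n_s`, `max_f`,
#'   `argmax_alpha`.
#' @export
glance.enrichment_curve <- function(x, ...) {
  tibble::tibble(
    s_prime_size = attr(x, "s_prime_size"),
    n_t = attr(x, "n_t"),
    n_s = attr(x, "n_s"),
    max_f = attr(x, "max_f"),
    argmax_alpha = attr(x, "argmax_alpha")
  )
}

#' Fold-enrichment curve plot
#'
#' @param object An [enrichment_curve()].
#' @param ... Unused.
#' @return A ggplot object; the dashed line marks the random-ranking
#'   expectation f = 1.
#' @export
autoplot.enrichment_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$alpha, y = .data$f)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", color = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(alpha ~ "(%)"), y = expression(f(alpha)),
      title = "Fold enrichment"
    ) +
    ggplot2::theme_minimal()
}

#' Read relation sets from TSV
#'
#' `read_relation_set()` expects two id columns (`id_a`, `id_b`);
#' `read_ranked_relations()` additionally a numeric `weight` column.
#'
#' @param path TSV file with a header row.
#' @return A [relation_set()] / [ranked_relations()].
#' @export
read_relation_set <- function(path) {
  relation_set(read_tsv_checked(path, c("id_a", "id_b")))
}

#' @rdname read_relation_set
#' @export
read_ranked_relations <- function(path) {
  tbl <- read_tsv_checked(path, c("id_a", "id_b", "weight"))
  tbl$weight <- as.numeric(tbl$weight)
  ranked_relations(tbl)
}
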