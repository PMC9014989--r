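# Weighted NASA-TLX scoring: pairwise-comparison weights over the six
# dimensions (each weight = number of pairs won, summing to 15) and the
# weighted workload score sum(rating * weight) / 15.

#' The six NASA-TLX dimensions
#' @return character vector: md, pd, td, op, ef, fr (mental demand, physical
#'   demand, temporal demand, own performance, effort, frustration).
#' @export
tlx_dimensions <- function() c("md", "pd", "td", "op", "ef", "fr")

#' All 15 unordered dimension pairs
#' @return data.frame with columns `a`, `b`.
#' @export
tlx_pairs <- function() {
  cmb <- utils::combn(tlx_dimensions(), 2)
  data.frame(a = cmb[1, ], b = cmb[2, ])
}

#' Derive dimension weights from pairwise choices
#'
#' Each of the 15 unordered pairs of dimensions must appear exactly once with
#' a winner drawn from that pair; a dimension's weight is the number of pairs
#' it won, so the weights always sum to 15.
#'
#' @param pair_choices data.frame with columns `a`, `b`, `winner` (15 rows).
#' @return named integer vector of weights (class `tlx_weights`).
#' @export
compute_weights <- function(pair_choices) {
  dims <- tlx_dimensions()
  req <- c("a", "b", "winner")
  if (!all(req %in% names(pair_choices)))
    stop("pair_choices needs columns a, b, winner")
  if (nrow(pair_choices) != 15L)
    stop("validation error: expected 15 pair choices, got ", nrow(pair_choices))
  key <- apply(pair_choices[, c("a", "b")], 1, function(r)
    paste(sort(r), collapse = ":"))
  want <- apply(tlx_pairs(), 1, function(r) paste(sort(r), collapse = ":"))
  missing <- setdiff(want, key)
  dup <- key[duplicated(key)]
  if (length(missing) || length(dup))
    stop("validation error: ",
         if (length(missing)) paste("missing pair(s)",
                                    paste(missing, collapse = ", ")) else "",
         if (length(dup)) paste(" duplicate pair(s)",
                                paste(unique(dup), collapse = ", ")) else "")
  bad <- !(pair_choices$winner == pair_choices$a |
             pair_choices$winner == pair_choices$b)
  if (any(bad))
    stop("validation error: winner not a member of its pair in row(s) ",
         paste(which(bad), collapse = ", "))
  w <- table(factor(pair_choices$winner, levels = dims))
  out <- stats::setNames(as.integer(w), dims)
  class(out) <- "tlx_weights"
  out
}

#' Weighted NASA-TLX workload score
#'
#' `overall = sum(rating_i * weight_i) / 15`, reported to 2 decimals; the
#' per-dimension weighted contributions are returned unrounded.
#'
#' @param rating named numeric vector of the six 0-100 ratings (names as in
#'   [tlx_dimensions()]).
#' @param weights a [compute_weights()] result (or named 0-5 integers summing
#'   to 15).
#' @return list with `overall` (rounded to 2 decimals), `overall_exact`, and
#'   `contributions`.
#' @export
weighted_score <- function(rating, weights) {
  dims <- tlx_dimensions()
  if (!all(dims %in% names(rating)))
    stop("validation error: rating must name all of ",
         paste(dims, collapse = ", "))
  r <- as.numeric(rating[dims])
  if (any(!is.finite(r)) || any(r < 0 | r > 100))
    stop("validation error: ratings must lie in [0, 100]")
  w <- as.numeric(unclass(weights)[dims])
  if (any(w < 0 | w > 5) || sum(w) != 15L || any(w != round(w)))
    stop("validation error: weights must be integers 0..5 summing to 15")
  contrib <- r * w
  overall <- sum(contrib) / 15
  list(overall = round(overall, 2), overall_exact = overall,
       contributions = stats::setNames(contrib, dims))
}
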