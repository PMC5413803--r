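#' @title Wrapper feature selection with best-first search
#'
#' @description
#' The wrapper approach scores a candidate feature subset by the
#' cross-validated performance of the very classifier that will use it:
#' here, merit = leave-one-out accuracy of the wrapped classifier
#' restricted to the subset's columns.  Best-first search keeps an open
#' list of subsets ordered by merit, repeatedly expands the most
#' promising one by single-feature additions (and deletions, in the
#' default bidirectional mode), and stops after a patience of
#' consecutive non-improving expansions.
#'
#' @name feature-selection
NULL

subset_key <- function(idx) {
  if (length(idx) == 0L) "{}" else paste(sort(idx), collapse = ",")
}

# zero-padded key so string order equals lexicographic index order
subset_order_key <- function(key) {
  vapply(strsplit(key, ",", fixed = TRUE), function(p) {
    if (length(p) == 0L || identical(p[1], "{}")) return("")
    paste(sprintf("%04d", as.integer(p)), collapse = ",")
  }, character(1))
}

#' Merit of a feature subset
#'
#' Leave-one-out accuracy of the wrapped classifier on the subset's
#' columns.  The empty subset is scored by the majority-class
#' proportion — the accuracy of always predicting the larger class.
#'
#' @param data a [labeled_dataset()].
#' @param subset integer feature indices (possibly empty).
#' @param spec a [classifier_spec()].
#' @param seed RNG seed forwarded to the per-fold trainers.
#' @return Merit in `[0, 1]`.
#' @export
evaluate_subset <- function(data, subset, spec, seed = 1) {
  stopifnot(inherits(data, "pdt_dataset"))
  if (length(subset) == 0L)
    return(max(mean(data$y == 1), mean(data$y == -1)))
  res <- loocv(subset_features(data, subset), spec, seed = seed)
  mean(res$predicted == res$actual)
}

rank_subsets <- function(merits, sizes, keys) {
  order(-merits, sizes, keys)
}

#' Best-first search over feature subsets
#'
#' Starts from the empty set; each expansion generates all single-feature
#' additions (and deletions when `direction = "bidirectional"`) of the
#' current best open node, evaluates the unseen ones (memoised — no
#' subset is ever evaluated twice) and pushes them onto the open list.
#' The search stops after `patience` consecutive expansions that fail to
#' improve on the best merit seen, or when the open list empties.  Merit
#' ties are broken toward the smaller subset, then lexicographic index
#' order.
#'
#' @param data a [labeled_dataset()].
#' @param spec a [classifier_spec()].
#' @param patience consecutive non-improving expansions tolerated
#'   (default 5).
#' @param direction `"bidirectional"` (default) or `"forward"` (additions
#'   only).
#' @param seed RNG seed forwarded to merit evaluation.
#' @return A list of class `pdt_selection`:
#'   \describe{
#'     \item{subset}{`list(indices, names, merit)` of the best subset.}
#'     \item{trace}{data frame of every evaluated subset (`key`, `size`,
#'       `merit`) in evaluation order.}
#'     \item{stopped}{`"patience_exhausted"` or `"space_exhausted"`.}
#'   }
#' @export
best_first_select <- function(data, spec, patience = 5,
                              direction = c("bidirectional", "forward"),
                              seed = 1) {
  stopifnot(inherits(data, "pdt_dataset"))
  direction <- match.arg(direction)
  m <- ncol(data$X)
  if (m < 1L) stop_pdt("need at least one feature", "pdt_data_error")

  visited <- new.env(parent = emptyenv())  # key -> list(idx, merit, order)
  n_eval <- 0L
  eval_node <- function(idx) {
    key <- subset_key(idx)
    hit <- get0(key, envir = visited, inherits = FALSE)
    if (!is.null(hit)) return(hit$merit)
    merit <- evaluate_subset(data, idx, spec, seed = seed)
    n_eval <<- n_eval + 1L
    assign(key, list(idx = sort(idx), merit = merit, order = n_eval),
           envir = visited)
    merit
  }

  start <- integer(0)
  best_merit <- eval_node(start)
  open_keys <- subset_key(start)
  expanded <- character(0)
  stale <- 0L
  stopped <- "space_exhausted"

  while (length(open_keys) > 0L) {
    nodes <- lapply(open_keys, get, envir = visited)
    merits <- vapply(nodes, `[[`, numeric(1), "merit")
    sizes <- vapply(nodes, function(nd) length(nd$idx), integer(1))
    pick <- rank_subsets(merits, sizes, subset_order_key(open_keys))[1L]
    cur <- nodes[[pick]]
    open_keys <- open_keys[-pick]
    expanded <- c(expanded, subset_key(cur$idx))

    children <- lapply(setdiff(seq_len(m), cur$idx),
                       function(j) sort(c(cur$idx, j)))
    if (direction == "bidirectional" && length(cur$idx) > 0L)
      children <- c(children, lapply(seq_along(cur$idx),
                                     function(j) cur$idx[-j]))
    improved <- FALSE
    for (child in children) {
      key <- subset_key(child)
      seen <- !is.null(get0(key, envir = visited, inherits = FALSE))
      merit <- eval_node(child)
      if (!seen) {
        open_keys <- c(open_keys, key)
        if (merit > best_merit + 1e-12) {
          best_merit <- merit
          improved <- TRUE
        }
      }
    }
    if (improved) stale <- 0L else stale <- stale + 1L
    if (stale >= patience) { stopped <- "patience_exhausted"; break }
  }

  all_nodes <- mget(ls(visited), envir = visited)
  trace <- data.frame(
    key = vapply(all_nodes, function(nd) subset_key(nd$idx), character(1)),
    size = vapply(all_nodes, function(nd) length(nd$idx), integer(1)),
    merit = vapply(all_nodes, `[[`, numeric(1), "merit"),
    order = vapply(all_nodes, `[[`, integer(1), "order"),
    row.names = NULL)
  trace <- trace[order(trace$order), , drop = FALSE]

  top <- abs(trace$merit - max(trace$merit)) < 1e-12
  cand <- trace[top, , drop = FALSE]
  pick <- order(cand$size, subset_order_key(cand$key))[1L]
  best_idx <- all_nodes[[match(cand$key[pick],
                               vapply(all_nodes, function(nd)
                                 subset_key(nd$idx), character(1)))]]$idx

  structure(list(
    subset = list(indices = best_idx,
                  names = data$feature_names[best_idx],
                  merit = max(trace$merit)),
    trace = trace, stopped = stopped, n_evaluated = n_eval),
    class = "pdt_selection")
}

#' @export
print.pdt_selection <- function(x, ...) {
  cat(sprintf("<pdt_selection> merit=%.3f, %d subsets evaluated (%s)\n",
              x$subset$merit, x$n_evaluated, x$stopped))
  cat("  features:", if (length(x$subset$names))
    paste(x$subset$names, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Cross-classifier selection summary
#'
#' Tabulates, per classifier family, which features were selected and
#' how many families selected each feature — one row per feature that at
#' least one family chose.
#'
#' @param selections named list of `pdt_selection` objects (names are the
#'   classifier families).
#' @param feature_names full feature-name vector.
#' @return A data frame with one column per classifier (`"X"` marks
#'   selection) and a trailing `n_classifiers` count, plus an attribute
#'   `n_features` giving the subset size per classifier.
#' @export
selection_report <- function(selections, feature_names = pdt_feature_names) {
  if (length(selections) == 0L)
    stop_pdt("no selections to report", "pdt_contract_error")
  chosen <- lapply(selections, function(s) s$subset$names)
  all_feats <- feature_names[feature_names %in% unique(unlist(chosen))]
  marks <- vapply(selections, function(s)
    ifelse(all_feats %in% s$subset$names, "X", ""),
    character(length(all_feats)))
  marks <- matrix(marks, nrow = length(all_feats),
                  dimnames = list(NULL, names(selections)))
  out <- data.frame(feature = all_feats, marks, check.names = FALSE)
  out$n_classifiers <- rowSums(marks == "X")
  attr(out, "n_features") <- vapply(selections, function(s)
    length(s$subset$indices), integer(1))
  out
}
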