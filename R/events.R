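# Maximum-likelihood inference of independent risk-differentiation
# events. A single ancestral event can pass a modified risk to every
# branch below it, so an event "explains" its branch and the whole
# subtree under it; the model log-likelihood is the sum of log null
# probabilities over the branches left unexplained, and the number of
# events is chosen by nested chi-squared likelihood-ratio tests.

#' Branches explained by a set of events
#'
#' An event on a branch explains the branch itself and every branch
#' descending from it (dependent, inherited differentiation).
#'
#' @param branches Branch table from [population_branches()].
#' @param events Character vector of event branch ids.
#' @return Character vector of explained branch ids.
#' @export
explained_branches <- function(branches, events) {
  if (length(events) == 0) return(character(0))
  unknown <- setdiff(events, branches$branch)
  if (length(unknown) > 0) {
    abort(paste0("unknown branch id(s): ", paste(unknown, collapse = ", ")))
  }
  dm <- branch_descent_matrix(branches)
  below <- rownames(dm)[rowSums(dm[, events, drop = FALSE]) > 0]
  union(events, below)
}

#' Log-likelihood of an event model
#'
#' `l = sum over unexplained branches of ln P(branch)`, where `P` holds
#' each branch's null probability of its observed deviation. Explained
#' branches (events and their subtrees) contribute nothing.
#'
#' @param p Named numeric vector of per-branch null probabilities (the
#'   empirical p-values of the differentiation test).
#' @param branches Branch table from [population_branches()].
#' @param events Character vector of event branch ids.
#' @return The log-likelihood (a non-positive number).
#' @export
event_log_likelihood <- function(p, branches, events = character(0)) {
  stopifnot(!is.null(names(p)))
  expl <- explained_branches(branches, events)
  sum(log(p[setdiff(branches$branch, expl)]))
}

# Admissibility: no event may sit inside another event's explained
# subtree (a nested event adds nothing).
is_admissible <- function(events, dm) {
  if (length(events) < 2) return(TRUE)
  !any(dm[events, events, drop = FALSE])
}

#' Best set of y event branches
#'
#' Finds the admissible set of `y` branches (no event a descendant of
#' another) maximising [event_log_likelihood()]. Exhaustive enumeration
#' by default; ties are broken toward the set explaining fewer branches,
#' then lexicographically. `method = "greedy"` adds one event at a time
#' (for trees where the exhaustive search is infeasible).
#'
#' @param p Named per-branch null probabilities.
#' @param branches Branch table from [population_branches()].
#' @param y Number of events (`y = 0` gives the empty model).
#' @param method `"exhaustive"` or `"greedy"`.
#' @param max_combinations Guard for the exhaustive search.
#' @return List with `events`, `log_lik`, `explained`.
#' @export
best_event_set <- function(p, branches, y,
                           method = c("exhaustive", "greedy"),
                           max_combinations = 2e6) {
  method <- match.arg(method)
  ids <- branches$branch
  p <- p[ids]
  if (y > length(ids)) {
    abort(sprintf("y = %d exceeds the %d testable branches", y, length(ids)))
  }
  if (y == 0) {
    return(list(events = character(0),
                log_lik = sum(log(p)), explained = character(0)))
  }
  dm <- branch_descent_matrix(branches)
  if (method == "exhaustive" && choose(length(ids), y) > max_combinations) {
    abort(sprintf(
      "exhaustive search over choose(%d, %d) sets is infeasible; use method = \"greedy\"",
      length(ids), y))
  }
  score_set <- function(events) {
    expl <- union(events, rownames(dm)[rowSums(dm[, events, drop = FALSE]) > 0])
    list(l = sum(log(p[setdiff(ids, expl)])), explained = expl)
  }
  if (method == "greedy") {
    events <- character(0)
    for (step in seq_len(y)) {
      cand <- setdiff(ids, events)
      cand <- cand[vapply(cand, function(b) is_admissible(c(events, b), dm),
                          logical(1))]
      if (length(cand) == 0) abort("no admissible branch left for another event")
      scores <- vapply(cand, function(b) score_set(c(events, b))$l, numeric(1))
      expl_n <- vapply(cand, function(b) length(score_set(c(events, b))$explained),
                       integer(1))
      best <- order(-scores, expl_n, cand)[1]
      events <- c(events, cand[best])
    }
    sc <- score_set(events)
    return(list(events = sort(events), log_lik = sc$l, explained = sc$explained))
  }
  combos <- utils::combn(ids, y, simplify = FALSE)
  combos <- combos[vapply(combos, is_admissible, logical(1), dm = dm)]
  if (length(combos) == 0) abort("no admissible event set of the requested size")
  scored <- lapply(combos, score_set)
  l <- vapply(scored, `[[`, numeric(1), "l")
  n_expl <- vapply(scored, function(s) length(s$explained), integer(1))
  key <- vapply(combos, function(e) paste(sort(e), collapse = "|"), character(1))
  best <- order(-l, n_expl, key)[1]
  list(events = sort(combos[[best]]), log_lik = l[best],
       explained = scored[[best]]$explained)
}

#' Likelihood-ratio test for the number of events
#'
#' `2 (l_n - l_{n-1})` is compared to a chi-squared distribution with one
#' degree of freedom. Stepping up from `n = 2`, the chosen number of
#' events is the last `n` before the first non-significant improvement.
#'
#' @param log_liks Numeric vector `l_1, l_2, ...` of maximised
#'   log-likelihoods for 1, 2, ... events (non-decreasing).
#' @param threshold Significance threshold for an extra event (default
#'   0.05).
#' @return List with `chosen_n` and `p` (the p-value for `n` vs `n - 1`
#'   events, `NA` for `n = 1`).
#' @export
lrt_event_count <- function(log_liks, threshold = 0.05) {
  n <- length(log_liks)
  if (n >= 2 && any(diff(log_liks) < -1e-8)) {
    abort("log-likelihood sequence is decreasing; the event search is inconsistent")
  }
  p <- c(NA_real_, if (n >= 2) {
    pchisq(2 * diff(log_liks), df = 1, lower.tail = FALSE)
  })
  chosen <- 1L
  for (i in seq_len(n)[-1]) {
    if (!is.na(p[i]) && p[i] < threshold) chosen <- i else break
  }
  list(chosen_n = chosen, p = p)
}

#' Infer independent risk-differentiation events on a tree
#'
#' Runs [best_event_set()] for `y = 1 .. max_events` on the branch
#' p-values of a differentiation test and picks the supported number of
#' events with the nested chi-squared LRT.
#'
#' @param test A branch-mode `drift_test` (from [test_differentiation()]),
#'   or a named p-value vector together with `branches`.
#' @param max_events Largest event count to fit.
#' @param alpha LRT significance threshold.
#' @param method Search method, see [best_event_set()].
#' @param branches Branch table; only needed when `test` is a bare
#'   p-value vector.
#' @return An `event_model`: list with `models` (tibble of `n_events`,
#'   `log_lik`, `lrt_p`, `events` list-column), `chosen_n`, `alpha`,
#'   `null_log_lik` (the zero-event model).
#' @export
infer_events <- function(test, max_events = 6, alpha = 0.05,
                         method = c("exhaustive", "greedy"),
                         branches = NULL) {
  method <- match.arg(method)
  if (inherits(test, "drift_test")) {
    if (test$mode != "branch") {
      abort("event inference needs a branch-mode differentiation test")
    }
    p <- setNames(test$results$p, test$results$branch)
    branches <- test$branches
  } else {
    p <- test
    if (is.null(branches)) abort("pass `branches` with a bare p-value vector")
  }
  max_events <- min(max_events, nrow(branches))
  # once an event set explains every branch, more events cannot improve
  # the likelihood (and admissibility can only force worse sets)
  fits <- list()
  for (y in seq_len(max_events)) {
    fits[[y]] <- best_event_set(p, branches, y, method = method)
    if (length(fits[[y]]$explained) == nrow(branches)) break
  }
  max_events <- length(fits)
  log_liks <- vapply(fits, `[[`, numeric(1), "log_lik")
  lrt <- lrt_event_count(log_liks, alpha)
  models <- tibble::tibble(
    n_events = seq_len(max_events),
    log_lik = log_liks,
    lrt_p = lrt$p,
    events = lapply(fits, `[[`, "events")
  )
  structure(
    list(models = models, chosen_n = lrt$chosen_n, alpha = alpha,
         null_log_lik = event_log_likelihood(p, branches, character(0))),
    class = "event_model"
  )
}

#' @export
print.event_model <- function(x, ...) {
  cat(sprintf("<event_model: %d independent event(s) supported at alpha = %g>\n",
              x$chosen_n, x$alpha))
  print(x$models, ...)
  invisible(x)
}
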