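#' Local discovery of a target's parents-and-children set (GLL-PC)
#'
#' Semi-interleaved HITON-PC: candidates marginally dependent on the target
#' are admitted one at a time in order of marginal association strength
#' (p-value ascending, ties by |statistic| descending, then name); after each
#' admission every tentative member is re-tested against all subsets of the
#' other tentative members up to size `max_k` and removed — with the
#' separating set recorded — the first time independence is found. A final
#' elimination sweep is repeated to a fixed point. With a faithful oracle
#' backend the result is exactly the target's parents and children in the
#' generating DAG.
#'
#' @param backend a [ci_backend()].
#' @param target variable name.
#' @param alpha significance threshold (default: the backend's).
#' @param max_k maximum conditioning-set size (default 3).
#' @param vars candidate variables (default: all backend variables).
#' @return a `tierpc_pcset`: list with `target`, `members` (sorted character
#'   vector), `sepsets` (named list keyed by unordered pair), `trace`
#'   (admission/removal log, each entry citing its triggering test) and
#'   `n_tests`.
#' @export
gll_pc <- function(backend, target, alpha = backend$alpha, max_k = 3L,
                   vars = backend$vars) {
  stopifnot(inherits(backend, "tierpc_ci_backend"))
  if (!target %in% backend$vars) {
    stop("target '", target, "' not found in data", call. = FALSE)
  }
  others <- setdiff(vars, target)
  if (length(others) < 1L) stop("need at least 2 variables", call. = FALSE)
  sepsets <- list()
  trace <- list()
  n_tests <- 0L
  note <- function(action, var, res) {
    trace[[length(trace) + 1L]] <<- list(action = action, var = var,
                                         test = res)
  }

  # marginal screen: rank candidates, reject marginal independencies with
  # the empty sepset
  marg <- lapply(others, function(v) backend$test(target, v, character()))
  n_tests <- n_tests + length(marg)
  pvals <- vapply(marg, function(r) r$p_value, 0)
  stats_ <- vapply(marg, function(r) abs(r$statistic), 0)
  dep <- !vapply(marg, function(r) r$independent, TRUE)
  for (i in which(!dep)) {
    sepsets[[pair_key(target, others[i])]] <- character()
    note("reject_marginal", others[i], marg[[i]])
  }
  ord <- order(pvals, -stats_, others)
  queue <- others[ord][dep[ord]]

  tpc <- character()  # tentative PC, in admission order

  # try to eliminate member z given subsets of current tpc \ {z}
  try_eliminate <- function(z) {
    rest <- setdiff(tpc, z)
    for (k in 0:min(max_k, length(rest))) {
      subs <- if (k == 0L) list(character()) else
        utils::combn(sort(rest), k, simplify = FALSE)
      for (S in subs) {
        res <- backend$test(target, z, S)
        n_tests <<- n_tests + 1L
        if (res$independent) {
          sepsets[[pair_key(target, z)]] <<- res$S
          note("remove", z, res)
          tpc <<- setdiff(tpc, z)
          return(TRUE)
        }
      }
    }
    FALSE
  }

  for (cand in queue) {
    tpc <- c(tpc, cand)
    note("admit", cand, marg[[match(cand, others)]])
    # re-test every tentative member against subsets of the current others
    for (z in tpc) try_eliminate(z)
  }

  # final elimination pass to a fixed point
  repeat {
    removed <- FALSE
    for (z in tpc) {
      if (try_eliminate(z)) removed <- TRUE
    }
    if (!removed) break
  }

  structure(
    list(target = target, members = sort(tpc), sepsets = sepsets,
         trace = trace, n_tests = n_tests, alpha = alpha, max_k = max_k),
    class = "tierpc_pcset"
  )
}

#' @export
print.tierpc_pcset <- function(x, ...) {
  cat(sprintf("PC set of %s (max_k=%d, %d tests): {%s}\n", x$target,
              x$max_k, x$n_tests, paste(x$members, collapse = ", ")))
  invisible(x)
}

#' Symmetry-correct a family of local PC sets
#'
#' Applies the AND rule: `y` stays a member of `PC(x)` only if `x` is also a
#' member of `PC(y)` (configurable to the more permissive OR rule). The AND
#' rule is the standard false-positive-controlling choice in local-to-global
#' learning. Removals are recorded in the `"removals"` attribute.
#'
#' @param pcsets named list of `tierpc_pcset`, one per variable.
#' @param rule `"AND"` (default) or `"OR"`.
#' @return the corrected named list, same shape as the input.
#' @export
symmetry_correct <- function(pcsets, rule = c("AND", "OR")) {
  rule <- match.arg(rule)
  vars <- names(pcsets)
  if (is.null(vars) || any(!nzchar(vars))) {
    stop("pcsets must be a named list keyed by variable", call. = FALSE)
  }
  removals <- data.frame(x = character(), y = character(),
                         stringsAsFactors = FALSE)
  if (rule == "OR") {
    for (x in vars) {
      for (y in pcsets[[x]]$members) {
        if (y %in% vars && !x %in% pcsets[[y]]$members) {
          pcsets[[y]]$members <- sort(c(pcsets[[y]]$members, x))
        }
      }
    }
  } else {
    for (x in vars) {
      keep <- vapply(pcsets[[x]]$members, function(y) {
        !y %in% vars || x %in% pcsets[[y]]$members
      }, TRUE)
      dropped <- pcsets[[x]]$members[!keep]
      if (length(dropped) > 0L) {
        removals <- rbind(removals, data.frame(
          x = x, y = dropped, stringsAsFactors = FALSE))
      }
      pcsets[[x]]$members <- pcsets[[x]]$members[keep]
    }
  }
  attr(pcsets, "removals") <- removals
  attr(pcsets, "rule") <- rule
  pcsets
}
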