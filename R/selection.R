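#' Sorted-response training/test split
#'
#' Orders the compounds by increasing activity, forces the most and least
#' active compounds into the training set, then walks the remaining
#' compounds in activity order assigning two of every three to the training
#' set and the third to the test set (approximately 70:30). Ties in activity
#' are broken lexicographically by id so the split is deterministic and
#' invariant to input order.
#'
#' @param ids compound ids.
#' @param y activity values (pIC50 or any monotone response).
#' @return list with character vectors `train` and `test` (ids).
#' @examples
#' split_sorted_response(sprintf("c%02d", 1:54), rnorm(54))
#' @export
split_sorted_response <- function(ids, y) {
  ids <- as.character(ids)
  if (length(ids) != length(y)) stop("ids and y lengths differ")
  if (length(ids) < 5L) stop("need at least 5 records to split")
  if (anyDuplicated(ids)) stop("duplicate ids")
  ord <- order(y, ids)
  ids_sorted <- ids[ord]
  n <- length(ids_sorted)
  train <- c(ids_sorted[1L], ids_sorted[n])
  middle <- ids_sorted[2:(n - 1L)]
  pos <- seq_along(middle) %% 3L
  test <- middle[pos == 0L]
  # keep the ratio at 70:30 - the cyclic walk can overshoot 30% by one, in
  # which case the last test-assigned compound returns to training
  # (54 compounds -> 38 train / 16 test)
  max_test <- floor(0.3 * n)
  if (length(test) > max_test) test <- test[seq_len(max_test)]
  train <- c(train, setdiff(middle, test))
  list(train = match_order(train, ids), test = match_order(test, ids))
}

# keep original input order within each set
match_order <- function(subset_ids, all_ids) {
  subset_ids[order(match(subset_ids, all_ids))]
}

#' Drop near-constant and highly inter-correlated descriptor columns
#'
#' Mirrors the usual pre-modelling exclusion rules: a column is dropped when
#' more than `constant_frac` of its values are identical (near-constant), and
#' from every pair with absolute Pearson correlation above `cor_limit` the
#' later column is dropped.
#'
#' @param table numeric data.frame of candidate descriptors.
#' @param constant_frac similarity threshold (default 0.80).
#' @param cor_limit inter-correlation threshold (default 0.95).
#' @return the reduced data.frame; dropped names in attribute `"dropped"`.
#' @export
descriptor_prefilter <- function(table, constant_frac = 0.80,
                                 cor_limit = 0.95) {
  table <- as.data.frame(table)
  num <- vapply(table, is.numeric, TRUE)
  tab <- table[, num, drop = FALSE]
  n <- nrow(tab)
  near_const <- vapply(tab, function(col) {
    max(table(col)) / n > constant_frac
  }, TRUE)
  dropped <- names(tab)[near_const]
  tab <- tab[, !near_const, drop = FALSE]
  if (ncol(tab) >= 2L) {
    cm <- abs(stats::cor(tab))
    keep <- rep(TRUE, ncol(tab))
    for (j in 2:ncol(tab)) {
      if (any(cm[j, seq_len(j - 1L)][keep[seq_len(j - 1L)]] > cor_limit))
        keep[j] <- FALSE
    }
    dropped <- c(dropped, names(tab)[!keep])
    tab <- tab[, keep, drop = FALSE]
  }
  structure(tab, dropped = dropped)
}

#' Genetic-algorithm variable subset selection
#'
#' Evolutionary search over descriptor subsets of size 1..`max_size`,
#' maximizing leave-one-out Q2 of the OLS fit (the hat-matrix shortcut makes
#' each evaluation a single least-squares solve). Subsets whose fitted model
#' contains any coefficient with a t-test p-value at or above `alpha` are
#' discarded. One GA run is performed per subset size; results are pooled
#' and ranked by Q2, with ties broken by fewer descriptors, then by R2.
#'
#' @param table data.frame of candidate descriptors.
#' @param y response vector.
#' @param max_size largest subset size (default 5).
#' @param generations GA generations per size (default 10000; scale down for
#'   interactive use - fitness converges far earlier on desk-size problems).
#' @param alpha per-coefficient significance threshold (default 0.05).
#' @param pop_size population size (default 50).
#' @param p_crossover uniform crossover probability per gene (default 0.5).
#' @param mutation_rate per-gene mutation probability (default `1/ncol`).
#' @param tournament tournament size for selection (default 3).
#' @param seed integer seed; required, recorded in the output.
#' @return data.frame ranked by fitness with columns `size`, `subset`
#'   (comma-joined names), `q2_loo`, `r2`; the best model as attribute
#'   `"model"`, the seed as attribute `"seed"`.
#' @export
ga_vss <- function(table, y, max_size = 5L, generations = 10000L,
                   alpha = 0.05, pop_size = 50L, p_crossover = 0.5,
                   mutation_rate = NULL, tournament = 3L, seed) {
  if (missing(seed)) stop("ga_vss requires an explicit integer seed")
  table <- as.data.frame(table)
  p <- ncol(table)
  if (p < 1L) stop("no candidate descriptors")
  n <- length(y)
  if (n <= max_size + 1L) stop("need n > max_size + 1")
  X_all <- as.matrix(table)
  if (is.null(mutation_rate)) mutation_rate <- 1 / p
  set.seed(seed)

  score_subset <- function(idx) {
    # returns c(q2, r2, ok) with ok = 0 for rank-deficient / insignificant
    X <- cbind(1, X_all[, idx, drop = FALSE])
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) return(c(-Inf, -Inf, 0))
    beta <- qr.coef(qr_x, y)
    res <- y - drop(X %*% beta)
    h <- rowSums(qr.Q(qr_x)^2)
    if (any(h > 1 - 1e-10)) return(c(-Inf, -Inf, 0))
    press <- sum((res / (1 - h))^2)
    tss <- sum((y - mean(y))^2)
    q2 <- 1 - press / tss
    r2 <- 1 - sum(res^2) / tss
    df <- n - length(idx) - 1L
    s2 <- sum(res^2) / df
    se <- sqrt(diag(s2 * chol2inv(qr.R(qr_x))))
    pv <- 2 * stats::pt(abs(beta / se), df, lower.tail = FALSE)
    ok <- all(pv[-1] < alpha)   # intercept exempt from the significance rule
    c(q2, r2, as.numeric(ok))
  }

  results <- list()
  remember <- function(idx, sc) {
    key <- paste(sort(idx), collapse = ",")
    if (is.null(results[[key]]) && is.finite(sc[1])) {
      results[[key]] <<- data.frame(
        size = length(idx),
        subset = paste(colnames(X_all)[sort(idx)], collapse = ","),
        q2_loo = sc[1], r2 = sc[2], significant = sc[3] == 1)
    }
  }

  for (size in seq_len(min(max_size, p))) {
    if (choose(p, size) <= pop_size * 4) {
      # small space: enumerate exhaustively instead of evolving
      combs <- utils::combn(p, size)
      for (ci in seq_len(ncol(combs))) {
        idx <- combs[, ci]
        remember(idx, score_subset(idx))
      }
      next
    }
    pop <- replicate(pop_size, sort(sample.int(p, size)), simplify = FALSE)
    fitness <- vapply(pop, function(idx) score_subset(idx)[1], 0)
    evals <- pop_size
    gen <- 0L
    while (gen < generations && evals < generations) {
      gen <- gen + 1L
      pick <- function() {
        cand <- sample.int(pop_size, tournament)
        cand[which.max(fitness[cand])]
      }
      p1 <- pop[[pick()]]; p2 <- pop[[pick()]]
      # uniform crossover on the union, then repair to exact size
      pool <- union(p1, p2)
      keep <- pool[stats::runif(length(pool)) < p_crossover]
      child <- unique(c(keep, sample(pool, size, replace = TRUE)))[seq_len(size)]
      child <- child[!is.na(child)]
      while (length(child) < size)
        child <- unique(c(child, sample.int(p, 1L)))
      # mutation: swap genes for random descriptors
      for (gpos in seq_along(child)) {
        if (stats::runif(1) < mutation_rate) {
          repl <- sample.int(p, 1L)
          if (!(repl %in% child)) child[gpos] <- repl
        }
      }
      child <- sort(child)
      sc <- score_subset(child)
      evals <- evals + 1L
      remember(child, sc)
      worst <- which.min(fitness)
      if (sc[1] > fitness[worst]) {
        pop[[worst]] <- child
        fitness[worst] <- sc[1]
      }
    }
    for (ii in seq_along(pop)) remember(pop[[ii]], score_subset(pop[[ii]]))
  }

  if (length(results) == 0L)
    stop("GA-VSS found no full-rank subset")
  tab <- do.call(rbind, results)
  tab <- tab[tab$significant, , drop = FALSE]
  if (nrow(tab) == 0L)
    stop("GA-VSS: every candidate subset has an insignificant coefficient ",
         "(p >= ", alpha, ")")
  tab <- tab[order(-tab$q2_loo, tab$size, -tab$r2), , drop = FALSE]
  rownames(tab) <- NULL
  best_names <- strsplit(tab$subset[1], ",", fixed = TRUE)[[1]]
  best <- qsar_mlr(table[, best_names, drop = FALSE], y = y)
  attr(tab, "model") <- best
  attr(tab, "seed") <- seed
  tab
}

#' Serialize a fitted model to JSON
#'
#' @param model a `qsar_mlr`.
#' @param path output file; when `NULL` the JSON string is returned.
#' @param seed optional provenance seed recorded alongside the model.
#' @return `path` (invisibly) or the JSON string.
#' @export
write_model_json <- function(model, path = NULL, seed = NULL) {
  obj <- list(intercept = unname(model$coefficients[1]),
              coefficients = as.list(model$coefficients[-1]),
              training = list(ids = model$ids, y_mean = model$y_mean,
                              tss = model$tss, n = model$n, k = model$k),
              provenance = list(seed = seed,
                                package = "qsarligand"))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Load a model written by [write_model_json()]
#'
#' @param path JSON file path.
#' @return a `qsar_mlr` (without the training design matrix).
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  beta <- c(`(Intercept)` = obj$intercept, unlist(obj$coefficients))
  structure(list(coefficients = beta, descriptors = names(beta)[-1],
                 X = NULL, y = NULL, fitted = NULL, residuals = NULL,
                 ids = obj$training$ids,
                 y_mean = obj$training$y_mean %||% NA_real_,
                 tss = obj$training$tss %||% NA_real_,
                 n = obj$training$n %||% NA_integer_,
                 k = length(beta) - 1L),
            class = "qsar_mlr")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
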