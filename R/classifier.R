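#' Build a labeled training set from the corpus by rule
#'
#' Positives are candidate linking concepts whose feature vectors show an
#' interaction with the starting concept (`f4 = 1` or `f6 = 1`), plus any
#' manual positives. Negatives are drawn as evenly as possible from three
#' categories: `too_general` (document frequency above the `dfq` quantile in
#' the MeSH-field index, or listed in `stop_concepts`),
#' `no_window_cooccurrence` (`f5 = 0`), and `cooccur_no_interaction`
#' (`f5 = 1` with `f4 = f6 = 0`). Classes are balanced by seeded
#' down-sampling.
#'
#' @param features feature matrix from [feature_matrix()] over the candidate
#'   linking concepts.
#' @param mesh_index `cooc_index` at scope `mesh_field` (for the DF rule).
#' @param dfq document-frequency quantile above which a concept counts as
#'   too general (default 0.99, i.e. top 1% of DF).
#' @param stop_concepts optional character vector of stop concepts.
#' @param manual_labels optional `data.frame` with columns `concept`,
#'   `label` (`"positive"`/`"negative"`) overriding the rules.
#' @param seed integer seed controlling the balancing down-sample.
#' @return a `data.frame`: the feature columns plus `label` and `provenance`.
#' @export
build_training_set <- function(features, mesh_index, dfq = 0.99,
                               stop_concepts = character(),
                               manual_labels = NULL, seed = 1L) {
  stopifnot(all(.feature_names %in% names(features)))
  feats <- features
  manual_pos <- character(); manual_neg <- character()
  if (!is.null(manual_labels)) {
    manual_labels$concept <- normalize_concept(manual_labels$concept)
    manual_pos <- manual_labels$concept[manual_labels$label == "positive"]
    manual_neg <- manual_labels$concept[manual_labels$label == "negative"]
  }

  df <- vapply(feats$concept, function(b) occ_count(mesh_index, b), integer(1))
  # quantile over the candidates' own DF distribution (the starting concept
  # would otherwise dominate small corpora); inclusive top tail, with a
  # median guard so flat DF distributions flag nothing as too general
  df_cut <- stats::quantile(df, probs = dfq, names = FALSE, type = 1)
  too_general <- (df >= df_cut & df > stats::median(df)) |
    feats$concept %in% stop_concepts

  auto_pos <- (feats$f4 == 1 | feats$f6 == 1) & !(feats$concept %in% manual_neg)
  is_pos <- auto_pos | feats$concept %in% manual_pos

  cat_tg <- !is_pos & too_general
  cat_nw <- !is_pos & !too_general & feats$f5 == 0
  cat_ni <- !is_pos & !too_general & feats$f5 == 1 & feats$f4 == 0 & feats$f6 == 0

  pos_idx <- which(is_pos)
  cats <- list(too_general = which(cat_tg),
               no_window_cooccurrence = which(cat_nw),
               cooccur_no_interaction = which(cat_ni))
  if (length(pos_idx) == 0L) {
    stop("training-set class empty: no positive instances ",
         "(no candidate interacts with the starting concept)", call. = FALSE)
  }
  n_neg_avail <- sum(lengths(cats))
  if (n_neg_avail == 0L) {
    stop("training-set class empty: no negative instances in any category ",
         "(too_general, no_window_cooccurrence, cooccur_no_interaction)",
         call. = FALSE)
  }

  n <- min(length(pos_idx), n_neg_avail)
  rng <- .seeded_rng(seed)
  pos_take <- sort(rng$sample(pos_idx, n))
  # round-robin across non-empty categories for an even draw
  nonempty <- cats[lengths(cats) > 0L]
  shuffled <- lapply(nonempty, function(ix) rng$sample(ix, length(ix)))
  neg_take <- integer()
  while (length(neg_take) < n) {
    for (k in seq_along(shuffled)) {
      if (length(neg_take) >= n) break
      if (length(shuffled[[k]]) > 0L) {
        neg_take <- c(neg_take, shuffled[[k]][1L])
        shuffled[[k]] <- shuffled[[k]][-1L]
      }
    }
  }
  neg_take <- sort(neg_take)

  prov <- rep(NA_character_, nrow(feats))
  prov[feats$concept %in% manual_pos] <- "manual"
  prov[is.na(prov) & auto_pos] <- "interaction_with_start"
  for (nm in names(cats)) prov[cats[[nm]]] <- nm
  prov[feats$concept %in% manual_neg] <- "manual"

  out <- feats[c(pos_take, neg_take), , drop = FALSE]
  out$label <- rep(c("positive", "negative"), c(length(pos_take), length(neg_take)))
  out$provenance <- prov[c(pos_take, neg_take)]
  rownames(out) <- NULL
  out
}

# self-contained RNG wrapper: does not disturb the global .Random.seed
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
    set.seed(seed)
    st <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    st
  })
  with_state <- function(fun) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    res <- fun()
    env$state <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    res
  }
  list(
    sample = function(x, size) with_state(function() {
      x[sample.int(length(x), size)]
    }),
    runif = function(n) with_state(function() stats::runif(n)),
    rpois = function(n, lambda) with_state(function() stats::rpois(n, lambda)),
    rbinom = function(n, size, prob) with_state(function() stats::rbinom(n, size, prob))
  )
}

#' Train the linking-concept classifier
#'
#' A linear margin classifier (L2-regularized squared-hinge primal SVM)
#' fitted by BFGS on per-feature standardized inputs. The fit is
#' deterministic: zero initialization and a fixed optimizer, so retraining
#' reproduces identical predictions.
#'
#' @param examples labeled training set from [build_training_set()] (feature
#'   columns plus `label`).
#' @param cost soft-margin cost parameter C (default 1).
#' @param seed integer recorded in the model metadata (the fit itself is
#'   deterministic).
#' @return a `linking_classifier` with weights, bias and scaling parameters.
#' @export
train_linking_classifier <- function(examples, cost = 1, seed = 1L) {
  stopifnot(all(.feature_names %in% names(examples)), "label" %in% names(examples))
  y <- ifelse(examples$label == "positive", 1, -1)
  if (length(unique(y)) < 2L) {
    stop("training needs both classes; got only ",
         unique(examples$label), call. = FALSE)
  }
  if (min(table(y)) < 2L) stop("need >= 2 examples per class", call. = FALSE)
  x <- as.matrix(examples[.feature_names])
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0 | is.na(scale_)] <- 1
  xs <- scale(x, center = center, scale = scale_)

  obj <- function(theta) {
    w <- theta[-1]; b <- theta[1]
    margin <- 1 - y * (xs %*% w + b)
    viol <- pmax(margin, 0)
    0.5 * sum(w^2) + cost * sum(viol^2)
  }
  grad <- function(theta) {
    w <- theta[-1]; b <- theta[1]
    margin <- 1 - y * (xs %*% w + b)
    active <- margin > 0
    gw <- w - 2 * cost * t(xs) %*% (y * margin * active)
    gb <- -2 * cost * sum(y * margin * active)
    c(gb, as.numeric(gw))
  }
  fit <- stats::optim(rep(0, ncol(xs) + 1L), obj, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  structure(
    list(weights = stats::setNames(fit$par[-1], .feature_names),
         bias = fit$par[1],
         center = center, scale = scale_,
         metadata = list(cost = cost, seed = seed,
                         converged = fit$convergence == 0,
                         loss = fit$value, kernel = "linear",
                         solver = "squared-hinge primal / BFGS")),
    class = "linking_classifier"
  )
}

#' @export
print.linking_classifier <- function(x, ...) {
  cat("<linking_classifier linear, C=", x$metadata$cost, ">\n", sep = "")
  print(round(x$weights, 4))
  cat("bias:", round(x$bias, 4), "\n")
  invisible(x)
}

#' Decision values of the linear classifier
#'
#' `w . x_std + b` on standardized features; sign gives the label.
#'
#' @param model a `linking_classifier`.
#' @param vectors a feature `data.frame` with columns `f1`...`f7`.
#' @return numeric vector of decision values.
#' @export
decision_values <- function(model, vectors) {
  if (!all(.feature_names %in% names(vectors))) {
    stop("feature schema mismatch: vectors must have columns ",
         paste(.feature_names, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(vectors[.feature_names])
  xs <- scale(x, center = model$center, scale = model$scale)
  as.numeric(xs %*% model$weights + model$bias)
}

#' Classify linking-concept feature vectors
#'
#' @inheritParams decision_values
#' @return character vector `"positive"`/`"negative"`, one per row,
#'   order preserved.
#' @export
classify_linking <- function(model, vectors) {
  if (nrow(vectors) == 0L) return(character())
  ifelse(decision_values(model, vectors) >= 0, "positive", "negative")
}
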