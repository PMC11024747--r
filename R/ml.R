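# Per-concept sequence-level binary classifiers over an uncased
# bag-of-words space: logistic regression (ridge), polynomial-kernel SVM
# (degree 2), AdaBoost (SAMME over depth-1 stumps) and gradient boosting.
#
# One model is trained per (family, concept) for every binary-classifiable
# concept -- 101 under the shipped ontology. Duration, sets and reps are
# numeric categories and are rejected here by construction.

#' Fit an uncased bag-of-words vocabulary
#'
#' Tokens are casefolded and split on non-alphanumeric runs; the vocabulary
#' is fitted on training texts only, with dense column indices. Unseen test
#' tokens map to nothing (an out-of-vocabulary test text becomes the zero
#' vector).
#'
#' @param train_texts Character vector of training sequence texts.
#' @return An object of class `rehab_vocab`.
#' @export
fit_vocabulary <- function(train_texts) {
  if (length(train_texts) == 0L) stop("empty training corpus")
  toks <- tokenize_text(train_texts)
  vocab <- sort(unique(unlist(toks, use.names = FALSE)))
  if (length(vocab) == 0L) stop("training corpus contains no tokens")
  structure(list(index = stats::setNames(seq_along(vocab), vocab)),
            class = "rehab_vocab")
}

#' @export
print.rehab_vocab <- function(x, ...) {
  cat("Uncased bag-of-words vocabulary:", length(x$index), "tokens\n")
  invisible(x)
}

#' Vectorize texts under a fitted vocabulary
#'
#' @param vocab A `rehab_vocab`.
#' @param texts Character vector.
#' @return A sparse document-by-token count matrix (`dgCMatrix`).
#' @export
bow_matrix <- function(vocab, texts) {
  stopifnot(inherits(vocab, "rehab_vocab"))
  toks <- tokenize_text(texts)
  ijx <- lapply(seq_along(toks), function(i) {
    idx <- vocab$index[toks[[i]]]
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) return(NULL)
    tb <- table(idx)
    cbind(i = i, j = as.integer(names(tb)), x = as.integer(tb))
  })
  ijx <- do.call(rbind, Filter(Negate(is.null), ijx))
  if (is.null(ijx)) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(length(texts), length(vocab$index))))
  }
  Matrix::sparseMatrix(i = ijx[, "i"], j = ijx[, "j"], x = ijx[, "x"],
                       dims = c(length(texts), length(vocab$index)))
}

# Balanced class weights: n / (K * n_k), sklearn-style.
balanced_class_weights <- function(y) {
  tab <- table(factor(y, levels = c(0, 1)))
  n <- length(y)
  c("0" = n / (2 * max(tab[["0"]], 1L)), "1" = n / (2 * max(tab[["1"]], 1L)))
}

#' Family-specific default hyperparameters
#'
#' LR: ridge-penalized binomial fit with balanced class weights and
#' convergence tolerance 1e-4. SVM: polynomial kernel of degree 2 with
#' balanced class weights. AdaBoost: 100 estimators; gradient boosting: 50
#' estimators (learning rate 0.1, depth-3 trees). Everything else stays at
#' the backing library's defaults.
#'
#' @param family One of `"lr"`, `"svm"`, `"ada"`, `"gb"`.
#' @return A named list of hyperparameters.
#' @export
default_hyperparameters <- function(family) {
  switch(match.arg(family, c("lr", "svm", "ada", "gb")),
    lr = list(tol = 1e-4, balanced = TRUE),
    svm = list(degree = 2L, balanced = TRUE, coef0 = 0),
    ada = list(n_estimators = 100L),
    gb = list(n_estimators = 50L, eta = 0.1, max_depth = 3L)
  )
}

#' Train one per-concept binary classifier
#'
#' @param vocab A fitted `rehab_vocab`.
#' @param texts Training sequence texts.
#' @param y Binary labels (0/1), one per text.
#' @param family One of `"lr"`, `"svm"`, `"ada"`, `"gb"`.
#' @param hyperparameters Overrides merged over [default_hyperparameters()].
#' @param allow_degenerate Fit a constant predictor when `y` is single-class
#'   instead of raising.
#' @return An object of class `rehab_concept_model`.
#' @export
train <- function(vocab, texts, y, family = c("lr", "svm", "ada", "gb"),
                  hyperparameters = list(), allow_degenerate = FALSE) {
  family <- match.arg(family)
  stopifnot(inherits(vocab, "rehab_vocab"), length(texts) == length(y))
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)))
  hp <- utils::modifyList(default_hyperparameters(family), hyperparameters)

  if (length(unique(y)) < 2L) {
    if (!allow_degenerate) {
      stop("single-class training labels (all ", unique(y),
           "); pass allow_degenerate = TRUE for a constant predictor")
    }
    return(structure(list(family = family, hyperparameters = hp,
                          constant = unique(y), fit = NULL, vocab = vocab),
                     class = "rehab_concept_model"))
  }

  x <- bow_matrix(vocab, texts)
  fit <- switch(family,
    lr = {
      w <- if (isTRUE(hp$balanced)) balanced_class_weights(y)[as.character(y)]
           else rep(1, length(y))
      w <- as.numeric(w)
      yy <- y
      xx <- if (ncol(x) < 2L) cbind(x, 0) else x  # glmnet needs >= 2 columns
      # glmnet refuses classes with a single observation; duplicating that
      # row at half weight leaves the weighted likelihood unchanged.
      for (cls in c(0L, 1L)) {
        idx <- which(yy == cls)
        if (length(idx) == 1L) {
          xx <- rbind(xx, xx[idx, , drop = FALSE])
          yy <- c(yy, cls)
          w[idx] <- w[idx] / 2
          w <- c(w, w[idx])
        }
      }
      glmnet::glmnet(xx, factor(yy, levels = c(0, 1)), family = "binomial",
                     alpha = 0, lambda = 1 / length(yy), thresh = hp$tol,
                     weights = w, standardize = FALSE)
    },
    svm = {
      cw <- if (isTRUE(hp$balanced)) balanced_class_weights(y) else NULL
      e1071::svm(as.matrix(x), factor(y, levels = c(0, 1)),
                 kernel = "polynomial", degree = hp$degree, coef0 = hp$coef0,
                 class.weights = cw, scale = FALSE)
    },
    ada = adaboost_fit(as.matrix(x), y, n_estimators = hp$n_estimators),
    gb = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
      # lambda = 0 / min_child_weight = 0: classic gradient-boosted trees
      # place no penalty on leaf values, unlike the xgboost defaults.
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                      eta = hp$eta, lambda = 0, min_child_weight = 0,
                      nthread = 1),
        data = dtrain, nrounds = hp$n_estimators, verbose = 0)
    }
  )
  structure(list(family = family, hyperparameters = hp, constant = NULL,
                 fit = fit, vocab = vocab),
            class = "rehab_concept_model")
}

#' @export
print.rehab_concept_model <- function(x, ...) {
  cat("Per-concept classifier [", x$family, "]",
      if (!is.null(x$constant)) paste0(" (degenerate, constant ", x$constant, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Predict with a per-concept classifier
#'
#' @param object A fitted `rehab_concept_model`.
#' @param texts Character vector of sequence texts.
#' @param ... Unused.
#' @return Integer 0/1 predictions.
#' @export
predict.rehab_concept_model <- function(object, texts, ...) {
  if (!is.null(object$constant)) return(rep(object$constant, length(texts)))
  if (is.null(object$fit)) stop("model has not been fitted")
  x <- bow_matrix(object$vocab, texts)
  out <- switch(object$family,
    lr = {
      xx <- if (ncol(x) < 2L) cbind(x, 0) else x
      as.integer(stats::predict(object$fit, xx, type = "response") >= 0.5)
    },
    svm = as.integer(as.character(stats::predict(object$fit, as.matrix(x)))),
    ada = adaboost_predict(object$fit, as.matrix(x)),
    gb = as.integer(stats::predict(
      object$fit, xgboost::xgb.DMatrix(x, nthread = 1)) >= 0.5)
  )
  as.integer(out)
}

# --- AdaBoost (SAMME, discrete) over depth-1 rpart stumps ----------------
# No installed package ships the classic stump-boosted AdaBoost, so the
# reweighting loop is implemented here directly; rpart supplies the weak
# learner.
adaboost_fit <- function(x, y, n_estimators = 100L) {
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$.y <- factor(y, levels = c(0, 1))
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  for (b in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = 1, cp = -1, minsplit = 2,
                          minbucket = 1, xval = 0, maxcompete = 0,
                          maxsurrogate = 0))
    pred <- stats::predict(fit, df, type = "class")
    miss <- pred != df$.y
    err <- sum(w[miss]) / sum(w)
    if (err <= 1e-10) {          # perfect stump: take it with a capped vote
      stumps[[length(stumps) + 1L]] <- fit
      alphas <- c(alphas, 10)
      break
    }
    if (err >= 0.5) break        # no better than chance; stop boosting
    alpha <- log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  if (length(stumps) == 0L) {    # fall back to the majority class
    maj <- as.integer(names(which.max(table(y))))
    return(list(stumps = list(), alphas = numeric(0), majority = maj,
                feature_names = names(df)[names(df) != ".y"]))
  }
  list(stumps = stumps, alphas = alphas, majority = NULL,
       feature_names = names(df)[names(df) != ".y"])
}

adaboost_predict <- function(model, x) {
  if (length(model$stumps) == 0L) return(rep(model$majority, nrow(x)))
  df <- as.data.frame(x)
  names(df) <- model$feature_names
  score <- rep(0, nrow(df))
  for (b in seq_along(model$stumps)) {
    pred <- as.integer(as.character(
      stats::predict(model$stumps[[b]], df, type = "class")))
    score <- score + model$alphas[b] * ifelse(pred == 1L, 1, -1)
  }
  as.integer(score > 0)
}

#' Train the full per-concept model bank
#'
#' One model slot per (family, concept) over every binary-classifiable
#' concept of the ontology -- numeric categories (duration, sets, reps) are
#' excluded by construction. Concepts whose training labels are single-class
#' are recorded as skipped and predict their constant training class.
#'
#' @param texts Training sequence texts.
#' @param labels A list (one element per text) of character vectors of gold
#'   concept ids.
#' @param ontology A loaded `rehab_ontology`.
#' @param families Model families to fit (default all four).
#' @param hyperparameters Named list of per-family overrides.
#' @return An object of class `rehab_model_bank` with elements `vocab`,
#'   `models` (family -> concept -> model) and `skipped` (data.frame).
#' @export
train_all <- function(texts, labels, ontology,
                      families = c("lr", "svm", "ada", "gb"),
                      hyperparameters = list()) {
  stopifnot(inherits(ontology, "rehab_ontology"),
            length(texts) == length(labels))
  if (length(texts) == 0L) stop("empty training set")
  families <- match.arg(families, c("lr", "svm", "ada", "gb"),
                        several.ok = TRUE)
  bad <- setdiff(unique(unlist(labels)), ontology$binary_ids)
  if (length(bad)) {
    stop("labels outside the binary concept universe (numeric categories ",
         "are unfit for binary classification): ", paste(bad, collapse = ", "))
  }
  vocab <- fit_vocabulary(texts)
  concepts <- ontology$binary_ids
  ymat <- vapply(concepts, function(cid)
    vapply(labels, function(l) as.integer(cid %in% l), integer(1)),
    integer(length(texts)))
  if (length(texts) == 1L) ymat <- matrix(ymat, nrow = 1L,
                                          dimnames = list(NULL, concepts))
  skipped <- list()
  models <- lapply(families, function(fam) {
    fam_models <- lapply(concepts, function(cid) {
      y <- ymat[, cid]
      if (length(unique(y)) < 2L) {
        skipped[[length(skipped) + 1L]] <<- data.frame(
          family = fam, concept_id = cid, reason = "single-class labels",
          stringsAsFactors = FALSE)
        train(vocab, texts, y, family = fam,
              hyperparameters = hyperparameters[[fam]] %||% list(),
              allow_degenerate = TRUE)
      } else {
        train(vocab, texts, y, family = fam,
              hyperparameters = hyperparameters[[fam]] %||% list())
      }
    })
    stats::setNames(fam_models, concepts)
  })
  names(models) <- families
  structure(list(
    vocab = vocab, models = models, concepts = concepts,
    skipped = if (length(skipped)) do.call(rbind, skipped) else
      data.frame(family = character(0), concept_id = character(0),
                 reason = character(0))
  ), class = "rehab_model_bank")
}

#' @export
print.rehab_model_bank <- function(x, ...) {
  cat("Per-concept model bank: ", length(x$models), " families x ",
      length(x$concepts), " concepts (", nrow(x$skipped),
      " degenerate slots)\n", sep = "")
  invisible(x)
}

#' Predict the per-concept binary matrix for one family
#'
#' @param bank A `rehab_model_bank` from [train_all()].
#' @param texts Sequence texts to classify.
#' @param family One fitted family name.
#' @return An integer 0/1 matrix, `length(texts)` rows by concept columns.
#' @export
predict_bank <- function(bank, texts, family) {
  stopifnot(inherits(bank, "rehab_model_bank"))
  if (!family %in% names(bank$models)) {
    stop("family '", family, "' was not fitted in this bank")
  }
  preds <- vapply(bank$concepts, function(cid)
    predict(bank$models[[family]][[cid]], texts),
    integer(length(texts)))
  if (length(texts) == 1L) preds <- matrix(preds, nrow = 1L,
                                           dimnames = list(NULL, bank$concepts))
  preds
}
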