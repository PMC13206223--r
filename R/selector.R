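#' Selector hyperparameters
#'
#' Defaults target the small-cohort setting: a single transformer layer
#' with 8 attention heads, token width 32, loss coefficients
#' `lambda1 = lambda2 = 1e-5`, Adam at learning rate `1e-4`, and 3500
#' full-batch epochs. `lambda1` weights the statistical (T-squared) loss,
#' `lambda2` an embedding-norm regularizer; the classification loss is
#' unit-weighted. `ridge` stabilizes the differentiable pooled-covariance
#' inverse inside the statistical loss.
#'
#' @param d_token Token embedding width (must be divisible by `n_heads`).
#' @param n_layers Number of encoder blocks.
#' @param n_heads Attention heads.
#' @param lr Adam learning rate.
#' @param epochs Full-batch training epochs.
#' @param lambda1,lambda2 Coefficients of the statistical loss and the
#'   embedding-norm regularizer.
#' @param ridge Covariance ridge inside the differentiable T-squared.
#' @param seed Integer seed for parameter initialization.
#' @return A `selector_hyperparams` object.
#' @export
selector_hyperparams <- function(d_token = 32L, n_layers = 1L, n_heads = 8L,
                                 lr = 1e-4, epochs = 3500L,
                                 lambda1 = 1e-5, lambda2 = 1e-5,
                                 ridge = 1e-3, seed = 1L) {
  stopifnot(d_token %% n_heads == 0L, n_layers >= 1L,
            lambda1 >= 0, lambda2 >= 0, ridge >= 0, lr > 0, epochs >= 1L)
  structure(list(d_token = as.integer(d_token), n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), lr = lr,
                 epochs = as.integer(epochs), lambda1 = lambda1,
                 lambda2 = lambda2, ridge = ridge, seed = as.integer(seed)),
            class = "selector_hyperparams")
}

schema_token_meta <- function(schema) {
  kinds <- schema_kinds(schema)
  ncat <- vapply(schema$specs, function(s)
    if (s$kind == "categorical") length(s$categories) else 0L, integer(1))
  list(kinds = as.integer(kinds == "categorical"), ncat = as.integer(ncat))
}

init_params <- function(schema, hp) {
  d <- hp$d_token; dff <- 4L * d
  sdw <- 1 / sqrt(d)
  rn <- function(...) matrix(stats::rnorm(prod(c(...)), sd = sdw), ...)
  nb_with_seed(hp$seed, {
    tok <- lapply(schema$specs, function(s) {
      if (s$kind == "categorical")
        list(emb = rn(d, length(s$categories)))
      else
        list(w = as.vector(rn(d, 1)), b = as.vector(rn(d, 1)))
    })
    layers <- lapply(seq_len(hp$n_layers), function(l) list(
      ln1_g = rep(1, d), ln1_b = rep(0, d),
      Wq = rn(d, d), bq = rep(0, d),
      Wk = rn(d, d), bk = rep(0, d),
      Wv = rn(d, d), bv = rep(0, d),
      Wo = rn(d, d), bo = rep(0, d),
      ln2_g = rep(1, d), ln2_b = rep(0, d),
      W1 = rn(d, dff), b1 = rep(0, dff),
      W2 = rn(dff, d), b2 = rep(0, d)))
    list(tok = tok, cls = as.vector(rn(d, 1)), layers = layers,
         head = list(w = as.vector(rn(d, 1)), b = 0))
  })
}

flatten_params <- function(params) {
  pieces <- list()
  for (tk in params$tok) {
    pieces[[length(pieces) + 1L]] <-
      if (!is.null(tk$emb)) as.vector(tk$emb) else c(tk$w, tk$b)
  }
  pieces[[length(pieces) + 1L]] <- params$cls
  for (l in params$layers) {
    pieces[[length(pieces) + 1L]] <- c(
      l$ln1_g, l$ln1_b, as.vector(l$Wq), l$bq, as.vector(l$Wk), l$bk,
      as.vector(l$Wv), l$bv, as.vector(l$Wo), l$bo, l$ln2_g, l$ln2_b,
      as.vector(l$W1), l$b1, as.vector(l$W2), l$b2)
  }
  pieces[[length(pieces) + 1L]] <- c(params$head$w, params$head$b)
  unlist(pieces, use.names = FALSE)
}

unflatten_params <- function(flat, schema, hp) {
  d <- hp$d_token; dff <- 4L * d
  off <- 0L
  take <- function(k) { v <- flat[(off + 1L):(off + k)]; off <<- off + k; v }
  tok <- lapply(schema$specs, function(s) {
    if (s$kind == "categorical")
      list(emb = matrix(take(d * length(s$categories)), d))
    else
      list(w = take(d), b = take(d))
  })
  cls <- take(d)
  layers <- lapply(seq_len(hp$n_layers), function(l) list(
    ln1_g = take(d), ln1_b = take(d),
    Wq = matrix(take(d * d), d), bq = take(d),
    Wk = matrix(take(d * d), d), bk = take(d),
    Wv = matrix(take(d * d), d), bv = take(d),
    Wo = matrix(take(d * d), d), bo = take(d),
    ln2_g = take(d), ln2_b = take(d),
    W1 = matrix(take(d * dff), d), b1 = take(dff),
    W2 = matrix(take(dff * d), dff), b2 = take(d)))
  head <- list(w = take(d), b = take(1L))
  stopifnot(off == length(flat))
  list(tok = tok, cls = cls, layers = layers, head = head)
}

new_selector <- function(flat, schema, hp, preprocessor, log) {
  structure(list(flat = flat, schema = schema, hp = hp,
                 preprocessor = preprocessor, log = log,
                 params = unflatten_params(flat, schema, hp)),
            class = "trained_selector")
}

#' Freshly initialized (untrained) selector
#'
#' Draws all tokenizer/encoder/head parameters from the seeded scaled-normal
#' initializer without any training. Used for null analyses on random
#' representations and as the starting point of [train_selector()].
#'
#' @param schema The cohort's `feature_schema`.
#' @param hp A [selector_hyperparams()].
#' @param preprocessor Optional `preprocessor_state` to attach.
#' @return A `trained_selector` with an empty training log.
#' @export
init_selector <- function(schema, hp = selector_hyperparams(),
                          preprocessor = NULL) {
  flat <- flatten_params(init_params(schema, hp))
  new_selector(flat, schema, hp, preprocessor,
               data.frame(epoch = integer(), l_cls = numeric(),
                          l_stat = numeric(), l_reg = numeric(),
                          total = numeric()))
}

#' @export
print.trained_selector <- function(x, ...) {
  cat("trained_selector:", length(x$schema$specs), "features, d_token =",
      x$hp$d_token, ",", x$hp$n_heads, "heads,", x$hp$n_layers, "layer(s),",
      nrow(x$log), "training epochs\n")
  invisible(x)
}

check_preprocessed <- function(tab) {
  if (!isTRUE(tab$standardized))
    stop("cohort must be preprocessed (apply_preprocessor) before tokenization",
         call. = FALSE)
}

#' Tokenize a cohort
#'
#' Maps each feature value to a `d_token`-dimensional learned vector: a
#' numeric (or binary) feature with value `x` maps to `x * w_j + b_j`; a
#' categorical feature maps to its category's embedding row. A shared learned
#' CLS vector is prepended as token 1. No positional encodings are used:
#' tokens carry their identity through their own parameters.
#'
#' @param tab A preprocessed `cohort_table`.
#' @param selector A `trained_selector` (or [init_selector()] output).
#' @return An `n x (p+1) x d_token` array; index 1 on the token axis is CLS.
#' @export
tokenize <- function(tab, selector) {
  stopifnot(inherits(tab, "cohort_table"), inherits(selector, "trained_selector"))
  check_preprocessed(tab)
  meta <- schema_token_meta(tab$schema)
  sel_tokenize(selector$flat, tab$values, meta$kinds, meta$ncat,
               selector$hp$d_token, selector$hp$n_layers)
}

#' Encode tokens with the self-attention block(s)
#'
#' Standard pre-norm multi-head self-attention with a feed-forward sublayer
#' (expansion factor 4, ReLU) and residual connections. Output shape equals
#' input shape; with no positional encodings the map is equivariant under
#' permutations of the feature tokens.
#'
#' @param tokens An `n x (p+1) x d_token` array from [tokenize()].
#' @param selector The selector carrying the encoder parameters.
#' @return Array of the same shape: contextually enriched representations.
#' @export
encode <- function(tokens, selector) {
  stopifnot(inherits(selector, "trained_selector"),
            length(dim(tokens)) == 3L,
            dim(tokens)[3] == selector$hp$d_token)
  meta <- schema_token_meta(selector$schema)
  sel_encode(selector$flat, tokens, meta$kinds, meta$ncat,
             selector$hp$d_token, selector$hp$n_heads, selector$hp$n_layers)
}

#' Classification logits from encoded tokens
#'
#' Affine map of the encoded CLS token to one scalar logit per sample;
#' the predicted event probability is `plogis(logit)`.
#'
#' @param encoded Output of [encode()].
#' @param selector The selector carrying the head parameters.
#' @return Numeric vector of logits, length `n`.
#' @export
classification_logit <- function(encoded, selector) {
  stopifnot(inherits(selector, "trained_selector"))
  cls <- encoded[, 1L, , drop = TRUE]
  if (is.null(dim(cls))) cls <- matrix(cls, nrow = 1L)
  as.vector(cls %*% selector$params$head$w) + selector$params$head$b
}

#' Differentiable statistical loss (reference implementation)
#'
#' `L_stat = -(1/p) * sum_j T2_ridge(j)` where `T2_ridge(j)` is the Hotelling
#' statistic on feature `j`'s encoded token vectors between outcome groups,
#' computed with pooled covariance `S + ridge * I`. This R implementation is
#' the module's reference surface; training uses the identical compiled form.
#'
#' @param encoded `n x (p+1) x d` encoded array.
#' @param outcome 0/1 outcome vector.
#' @param ridge Covariance ridge (> 0 recommended inside a loss).
#' @return Scalar loss (0 when all representations coincide; decreases as
#'   group separation grows).
#' @export
statistical_loss <- function(encoded, outcome, ridge = 1e-3) {
  p <- dim(encoded)[2] - 1L
  if (min(table(factor(outcome, levels = 0:1))) < 2L)
    stop("each outcome class needs >= 2 samples", call. = FALSE)
  t2s <- vapply(seq_len(p), function(j) {
    Ej <- encoded[, j + 1L, ]
    as.numeric(hotelling_t2(Ej[outcome == 0L, , drop = FALSE],
                            Ej[outcome == 1L, , drop = FALSE], ridge = ridge))
  }, numeric(1))
  -mean(t2s)
}

bce_loss <- function(logits, outcome) {
  # numerically stable binary cross-entropy with logits
  mean(ifelse(logits > 0,
              logits * (1 - outcome) + log1p(exp(-logits)),
              -outcome * logits + log1p(exp(logits))))
}

#' Joint training objective
#'
#' `L_total = L_cls + lambda1 * L_stat + lambda2 * R` with `L_cls` the binary
#' cross-entropy between `plogis(logits)` and the outcome and `R` the mean
#' (over samples) squared norm of the input token embeddings.
#'
#' @param logits Length-`n` logits.
#' @param outcome 0/1 outcomes.
#' @param encoded Encoded token array (for the statistical term).
#' @param hp A [selector_hyperparams()] supplying `lambda1`, `lambda2`,
#'   `ridge`.
#' @param tokens Input token array (for the regularizer); may be omitted when
#'   `lambda2 = 0`.
#' @return Scalar total loss.
#' @export
total_loss <- function(logits, outcome, encoded, hp, tokens = NULL) {
  l_cls <- bce_loss(logits, outcome)
  l_stat <- if (hp$lambda1 != 0) statistical_loss(encoded, outcome, hp$ridge) else 0
  l_reg <- if (hp$lambda2 != 0) {
    if (is.null(tokens)) stop("tokens required when lambda2 > 0", call. = FALSE)
    sum(tokens^2) / dim(tokens)[1]
  } else 0
  l_cls + hp$lambda1 * l_stat + hp$lambda2 * l_reg
}

#' Evaluate the joint objective (and its gradient) at a selector's parameters
#'
#' Thin wrapper over the compiled forward/backward pass; used by
#' [train_selector()] and by gradient-correctness checks.
#'
#' @param selector A `trained_selector`.
#' @param tab A preprocessed `cohort_table`.
#' @param want_grad Also return the analytic gradient (flat layout).
#' @param want_encoded Also return the encoded array.
#' @param flat Optional parameter vector overriding `selector$flat`.
#' @return List with `loss`, `l_cls`, `l_stat`, `l_reg`, `logits`, `t2`,
#'   and optionally `grad`, `encoded`.
#' @export
selector_objective <- function(selector, tab, want_grad = FALSE,
                               want_encoded = FALSE, flat = NULL) {
  check_preprocessed(tab)
  meta <- schema_token_meta(tab$schema)
  hp <- selector$hp
  sel_eval(if (is.null(flat)) selector$flat else flat,
           tab$values, meta$kinds, meta$ncat, as.integer(tab$outcome),
           hp$d_token, hp$n_heads, hp$n_layers,
           hp$lambda1, hp$lambda2, hp$ridge, want_grad, want_encoded)
}

#' Train the selector
#'
#' Full-batch Adam for `hp$epochs` steps on the joint objective. If the
#' supplied cohort is raw, a preprocessor is fitted on the full cohort and
#' applied (the selector's single fit has no held-out split); inside the
#' classifier benchmark preprocessing is instead fitted per training split.
#' Training is deterministic given `hp$seed`.
#'
#' @param tab A `cohort_table` (raw or already preprocessed) with both
#'   outcome classes present.
#' @param hp A [selector_hyperparams()].
#' @return A `trained_selector` with the attached preprocessor state and a
#'   per-epoch training log (`l_cls`, `l_stat`, `l_reg`, `total`).
#' @export
train_selector <- function(tab, hp = selector_hyperparams()) {
  stopifnot(inherits(tab, "cohort_table"))
  if (length(unique(tab$outcome)) < 2L)
    stop("both outcome classes must be present", call. = FALSE)
  state <- NULL
  if (!isTRUE(tab$standardized)) {
    state <- fit_preprocessor(tab)
    tab <- apply_preprocessor(state, tab)
  }
  sel <- init_selector(tab$schema, hp, preprocessor = state)
  par <- sel$flat
  m <- v <- numeric(length(par))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  log <- matrix(NA_real_, hp$epochs, 4L,
                dimnames = list(NULL, c("l_cls", "l_stat", "l_reg", "total")))
  for (e in seq_len(hp$epochs)) {
    res <- tryCatch(
      selector_objective(sel, tab, want_grad = TRUE, flat = par),
      error = function(err)
        stop("training diverged at epoch ", e, ": ", conditionMessage(err),
             call. = FALSE))
    log[e, ] <- c(res$l_cls, res$l_stat, res$l_reg, res$loss)
    gr <- res$grad
    m <- b1 * m + (1 - b1) * gr
    v <- b2 * v + (1 - b2) * gr^2
    mhat <- m / (1 - b1^e)
    vhat <- v / (1 - b2^e)
    par <- par - hp$lr * mhat / (sqrt(vhat) + eps)
  }
  new_selector(par, tab$schema, hp, state,
               cbind(data.frame(epoch = seq_len(hp$epochs)),
                     as.data.frame(log)))
}

#' Hyperparameter sensitivity sweep
#'
#' Trains the selector over a grid of hyperparameter settings and reports,
#' per setting, the final loss components and the size of the selected
#' feature set at `alpha`.
#'
#' @param tab A `cohort_table`.
#' @param grid Data frame whose columns are a subset of
#'   `lr, lambda1, lambda2, d_token, n_heads, epochs`; one row per setting.
#' @param base Baseline [selector_hyperparams()] supplying unswept values.
#' @param alpha Significance level for the post-hoc selection.
#' @return `grid` augmented with `l_cls`, `l_stat`, `total`, `n_selected`.
#' @export
sweep_selector <- function(tab, grid, base = selector_hyperparams(),
                           alpha = 0.05) {
  out <- grid
  out$l_cls <- out$l_stat <- out$total <- NA_real_
  out$n_selected <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    hp <- unclass(base)
    for (nm in names(grid)) hp[[nm]] <- grid[[nm]][i]
    hp <- do.call(selector_hyperparams, hp)
    fit <- train_selector(tab, hp)
    last <- fit$log[nrow(fit$log), ]
    pre <- if (is.null(fit$preprocessor)) tab
           else apply_preprocessor(fit$preprocessor, tab)
    rep <- feature_significance(fit, pre, alpha = alpha)
    out$l_cls[i] <- last$l_cls; out$l_stat[i] <- last$l_stat
    out$total[i] <- last$total
    out$n_selected[i] <- length(rep$selected)
  }
  out
}
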