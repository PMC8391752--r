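## Compact recurrent sequence classifiers for next-visit prediction.
##
## A reference implementation in plain matrix algebra: an LSTM cell with
## analytic backpropagation through time, composed into five architectures
## (LSTM, bidirectional, 2-layer stack, bidirectional stack, additive
## attention pooling), trained with Adam on minibatches bucketed by
## sequence length. Gradients are verified against finite differences in
## the test suite. Sized for desk-scale cohorts, not GPU workloads.

GATE <- function(H) list(i = 1:H, f = (H + 1):(2 * H),
                         g = (2 * H + 1):(3 * H), o = (3 * H + 1):(4 * H))

lstm_cell_init <- function(d, h) {
  r <- sqrt(6 / (d + 4 * h))
  b <- rep(0, 4 * h)
  b[GATE(h)$f] <- 1 # forget-gate bias: remember by default
  list(W = matrix(runif(d * 4 * h, -r, r), d, 4 * h),
       U = matrix(runif(h * 4 * h, -r, r), h, 4 * h),
       b = b)
}

## xs: list over time of B x D matrices. reverse = process t = T..1.
lstm_forward <- function(cell, xs, reverse = FALSE) {
  Tn <- length(xs)
  B <- nrow(xs[[1]])
  H <- nrow(cell$U)
  g <- GATE(H)
  h <- matrix(0, B, H)
  cc <- matrix(0, B, H)
  hs <- vector("list", Tn)
  cache <- vector("list", Tn)
  for (t in if (reverse) rev(seq_len(Tn)) else seq_len(Tn)) {
    A <- xs[[t]] %*% cell$W + h %*% cell$U +
      matrix(cell$b, B, 4 * H, byrow = TRUE)
    gi <- plogis(A[, g$i, drop = FALSE])
    gf <- plogis(A[, g$f, drop = FALSE])
    gg <- tanh(A[, g$g, drop = FALSE])
    go <- plogis(A[, g$o, drop = FALSE])
    c_new <- gf * cc + gi * gg
    tc <- tanh(c_new)
    cache[[t]] <- list(i = gi, f = gf, g = gg, o = go,
                       c_prev = cc, h_prev = h, tc = tc)
    h <- go * tc
    cc <- c_new
    hs[[t]] <- h
  }
  list(hs = hs, h_last = h, cache = cache)
}

## dhs: list over time of external gradients on h_t (matrices, zeros allowed)
lstm_backward <- function(cell, xs, fw, dhs, reverse = FALSE) {
  Tn <- length(xs)
  B <- nrow(xs[[1]])
  H <- nrow(cell$U)
  dW <- cell$W * 0
  dU <- cell$U * 0
  db <- cell$b * 0
  dxs <- vector("list", Tn)
  dh <- matrix(0, B, H)
  dc <- matrix(0, B, H)
  for (t in if (reverse) seq_len(Tn) else rev(seq_len(Tn))) {
    ca <- fw$cache[[t]]
    dh_t <- dh + dhs[[t]]
    do_ <- dh_t * ca$tc
    dct <- dc + dh_t * ca$o * (1 - ca$tc^2)
    di <- dct * ca$g
    dg <- dct * ca$i
    df <- dct * ca$c_prev
    dc <- dct * ca$f
    dA <- cbind(di * ca$i * (1 - ca$i),
                df * ca$f * (1 - ca$f),
                dg * (1 - ca$g^2),
                do_ * ca$o * (1 - ca$o))
    dW <- dW + crossprod(xs[[t]], dA)
    dU <- dU + crossprod(ca$h_prev, dA)
    db <- db + colSums(dA)
    dh <- dA %*% t(cell$U)
    dxs[[t]] <- dA %*% t(cell$W)
  }
  list(W = dW, U = dU, b = db, dxs = dxs)
}

SEQ_FAMILIES <- c("lstm", "bilstm", "stack_lstm", "stack_bilstm",
                  "attention_lstm")

seq_params_init <- function(family, d, hidden, attention_size) {
  p <- list(f1 = lstm_cell_init(d, hidden))
  rep_width <- hidden
  if (family %in% c("bilstm", "stack_bilstm")) {
    p$b1 <- lstm_cell_init(d, hidden)
    rep_width <- 2 * hidden
  }
  if (family == "stack_lstm") {
    p$f2 <- lstm_cell_init(hidden, hidden)
  }
  if (family == "stack_bilstm") {
    p$f2 <- lstm_cell_init(2 * hidden, hidden)
    rep_width <- hidden
  }
  if (family == "attention_lstm") {
    ra <- sqrt(6 / (hidden + attention_size))
    p$att <- list(
      Wa = matrix(runif(hidden * attention_size, -ra, ra),
                  hidden, attention_size),
      ba = rep(0, attention_size),
      va = runif(attention_size, -ra, ra)
    )
  }
  p$head <- list(w = matrix(runif(rep_width, -0.1, 0.1), rep_width, 1),
                 b = 0)
  p
}

seq_forward <- function(family, p, xs) {
  B <- nrow(xs[[1]])
  st <- list()
  if (family == "lstm") {
    st$f1 <- lstm_forward(p$f1, xs)
    r <- st$f1$h_last
  } else if (family == "bilstm") {
    st$f1 <- lstm_forward(p$f1, xs)
    st$b1 <- lstm_forward(p$b1, xs, reverse = TRUE)
    r <- cbind(st$f1$h_last, st$b1$h_last)
  } else if (family == "stack_lstm") {
    st$f1 <- lstm_forward(p$f1, xs)
    st$f2 <- lstm_forward(p$f2, st$f1$hs)
    r <- st$f2$h_last
  } else if (family == "stack_bilstm") {
    st$f1 <- lstm_forward(p$f1, xs)
    st$b1 <- lstm_forward(p$b1, xs, reverse = TRUE)
    st$concat <- mapply(cbind, st$f1$hs, st$b1$hs, SIMPLIFY = FALSE)
    st$f2 <- lstm_forward(p$f2, st$concat)
    r <- st$f2$h_last
  } else { # attention_lstm: additive attention pooling over the outputs
    st$f1 <- lstm_forward(p$f1, xs)
    st$us <- lapply(st$f1$hs, function(h) {
      tanh(sweep(h %*% p$att$Wa, 2, p$att$ba, "+"))
    })
    es <- vapply(st$us, function(u) as.numeric(u %*% p$att$va), numeric(B))
    es <- matrix(es, nrow = B)
    alpha <- exp(es - apply(es, 1, max))
    st$alpha <- alpha / rowSums(alpha)
    r <- Reduce(`+`, lapply(seq_along(xs), function(t) {
      st$f1$hs[[t]] * st$alpha[, t]
    }))
  }
  logits <- as.numeric(r %*% p$head$w) + p$head$b
  list(r = r, logits = logits, prob = plogis(logits), state = st)
}

zero_like <- function(xs) lapply(xs, function(x) x * 0)

## mean binary cross-entropy gradient through head and architecture
seq_backward <- function(family, p, xs, fw, y) {
  B <- length(y)
  H <- nrow(p$f1$U)
  dlogit <- matrix((fw$prob - y) / B, ncol = 1)
  grads <- list(head = list(w = crossprod(fw$r, dlogit),
                            b = sum(dlogit)))
  dr <- dlogit %*% t(p$head$w)
  st <- fw$state
  Tn <- length(xs)
  if (family == "lstm") {
    dhs <- zero_like(st$f1$hs)
    dhs[[Tn]] <- dr
    bk <- lstm_backward(p$f1, xs, st$f1, dhs)
    grads$f1 <- bk[c("W", "U", "b")]
  } else if (family == "bilstm") {
    dhs_f <- zero_like(st$f1$hs)
    dhs_b <- zero_like(st$b1$hs)
    dhs_f[[Tn]] <- dr[, 1:H, drop = FALSE]
    dhs_b[[1]] <- dr[, (H + 1):(2 * H), drop = FALSE]
    grads$f1 <- lstm_backward(p$f1, xs, st$f1, dhs_f)[c("W", "U", "b")]
    grads$b1 <- lstm_backward(p$b1, xs, st$b1, dhs_b,
                              reverse = TRUE)[c("W", "U", "b")]
  } else if (family == "stack_lstm") {
    dhs2 <- zero_like(st$f2$hs)
    dhs2[[Tn]] <- dr
    bk2 <- lstm_backward(p$f2, st$f1$hs, st$f2, dhs2)
    grads$f2 <- bk2[c("W", "U", "b")]
    grads$f1 <- lstm_backward(p$f1, xs, st$f1, bk2$dxs)[c("W", "U", "b")]
  } else if (family == "stack_bilstm") {
    dhs2 <- zero_like(st$f2$hs)
    dhs2[[Tn]] <- dr
    bk2 <- lstm_backward(p$f2, st$concat, st$f2, dhs2)
    grads$f2 <- bk2[c("W", "U", "b")]
    dhs_f <- lapply(bk2$dxs, function(d) d[, 1:H, drop = FALSE])
    dhs_b <- lapply(bk2$dxs, function(d) d[, (H + 1):(2 * H), drop = FALSE])
    grads$f1 <- lstm_backward(p$f1, xs, st$f1, dhs_f)[c("W", "U", "b")]
    grads$b1 <- lstm_backward(p$b1, xs, st$b1, dhs_b,
                              reverse = TRUE)[c("W", "U", "b")]
  } else { # attention_lstm
    hs <- st$f1$hs
    dalpha <- vapply(seq_len(Tn), function(t) rowSums(dr * hs[[t]]),
                     numeric(nrow(dr)))
    dalpha <- matrix(dalpha, nrow = nrow(dr))
    de <- st$alpha * (dalpha - rowSums(st$alpha * dalpha))
    dWa <- p$att$Wa * 0
    dba <- p$att$ba * 0
    dva <- p$att$va * 0
    dhs <- zero_like(hs)
    for (t in seq_len(Tn)) {
      dhs[[t]] <- dhs[[t]] + dr * st$alpha[, t]
      du <- matrix(de[, t], ncol = 1) %*% matrix(p$att$va, nrow = 1) # B x A
      dpre <- du * (1 - st$us[[t]]^2)
      dWa <- dWa + crossprod(hs[[t]], dpre)
      dba <- dba + colSums(dpre)
      dva <- dva + as.numeric(crossprod(st$us[[t]], de[, t]))
      dhs[[t]] <- dhs[[t]] + dpre %*% t(p$att$Wa)
    }
    grads$att <- list(Wa = dWa, ba = dba, va = dva)
    grads$f1 <- lstm_backward(p$f1, xs, st$f1, dhs)[c("W", "U", "b")]
  }
  grads
}

seq_loss <- function(prob, y) {
  eps <- 1e-12
  -mean(y * log(prob + eps) + (1 - y) * log(1 - prob + eps))
}

## recursive map over parameter trees (leaves are numeric arrays)
tree_map <- function(f, ...) {
  ts <- list(...)
  if (is.list(ts[[1]])) {
    out <- lapply(seq_along(ts[[1]]), function(i) {
      do.call(tree_map, c(list(f), lapply(ts, `[[`, i)))
    })
    names(out) <- names(ts[[1]])
    out
  } else {
    do.call(f, ts)
  }
}

#' Recurrent architecture specification
#'
#' @param family One of `"lstm"`, `"bilstm"` (bidirectional),
#'   `"stack_lstm"` (two layers), `"stack_bilstm"` (bidirectional first
#'   layer under a second layer), `"attention_lstm"` (additive attention
#'   pooling over the recurrent outputs).
#' @param hidden Hidden units per direction and layer.
#' @param epochs Training epochs; the parameters retained are those of the
#'   epoch with the highest validation accuracy.
#' @param batch_size Minibatch size (batches are bucketed by sequence
#'   length, so no padding is needed).
#' @param learn_rate Adam learning rate.
#' @param attention_size Attention projection width (attention family
#'   only).
#' @param seed Integer seed; training is deterministic given the seed.
#' @return An `arch_spec` object for [train_sequence_model()].
#' @export
arch_spec <- function(family = SEQ_FAMILIES, hidden = 16, epochs = 30,
                      batch_size = 128, learn_rate = 0.02,
                      attention_size = 8, seed = 1) {
  family <- match.arg(family)
  if (any(c(hidden, epochs, batch_size, attention_size) < 1)) {
    abort("hidden, epochs, batch_size and attention_size must be >= 1")
  }
  structure(list(family = family, hidden = as.integer(hidden),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learn_rate = learn_rate,
                 attention_size = as.integer(attention_size), seed = seed),
            class = "arch_spec")
}

sample_width <- function(samples) {
  widths <- unique(vapply(samples$input, ncol, integer(1)))
  if (length(widths) > 1) {
    abort(sprintf("inconsistent step widths among samples: %s",
                  paste(widths, collapse = ", ")))
  }
  widths
}

## stack a set of T-step samples into a list over time of B x D matrices
stack_batch <- function(inputs) {
  Tn <- nrow(inputs[[1]])
  lapply(seq_len(Tn), function(t) {
    do.call(rbind, lapply(inputs, function(m) m[t, , drop = FALSE]))
  })
}

## per-channel standardisation fitted on the training samples: timing
## channels (months) and raw features live on very different scales, and
## recurrent nets train poorly on unscaled inputs
fit_input_scaling <- function(samples) {
  all_rows <- do.call(rbind, samples$input)
  centre <- colMeans(all_rows)
  scale <- apply(all_rows, 2, sd)
  scale[!is.finite(scale) | scale < 1e-8] <- 1
  list(centre = centre, scale = scale)
}

apply_input_scaling <- function(xs, scaling) {
  if (is.null(scaling)) return(xs)
  lapply(xs, function(x) {
    sweep(sweep(x, 2, scaling$centre), 2, scaling$scale, "/")
  })
}

batch_scores <- function(family, p, samples, scaling = NULL) {
  scores <- numeric(nrow(samples))
  for (Tn in unique(samples$n_steps)) {
    idx <- which(samples$n_steps == Tn)
    xs <- apply_input_scaling(stack_batch(samples$input[idx]), scaling)
    scores[idx] <- seq_forward(family, p, xs)$prob
  }
  scores
}

#' Train a recurrent next-visit classifier
#'
#' Minimises mean binary cross-entropy with Adam. Samples are bucketed by
#' sequence length; each epoch shuffles samples within buckets and visits
#' buckets in random order. After every epoch the validation accuracy (at
#' threshold 0.5) is recorded, and the returned model carries the
#' parameters of the best-validation epoch (first epoch on ties).
#'
#' @param train,val Non-empty `fld_samples` with a common step width.
#' @param spec An [arch_spec()].
#' @return An `fld_seq_model`: parameters, `best_epoch`, and a `history`
#'   tibble (`epoch`, `train_loss`, `val_accuracy`); see [predict()],
#'   [tidy()], [glance()], [autoplot()].
#' @export
train_sequence_model <- function(train, val, spec = arch_spec()) {
  if (nrow(train) == 0 || nrow(val) == 0) {
    abort("train and val sample sets must be non-empty")
  }
  d <- sample_width(train)
  if (sample_width(val) != d) {
    abort("train and val step widths differ")
  }
  y_all <- as.integer(train$target == "FLD")
  y_val <- as.integer(val$target == "FLD")
  scaling <- fit_input_scaling(train)

  with_preserved_seed(spec$seed, {
    p <- seq_params_init(spec$family, d, spec$hidden, spec$attention_size)
    m <- tree_map(function(x) x * 0, p)
    v <- tree_map(function(x) x * 0, p)
    step <- 0L
    b1 <- 0.9
    b2 <- 0.999
    best <- list(acc = -Inf, epoch = NA_integer_, params = p)
    history <- vector("list", spec$epochs)

    for (epoch in seq_len(spec$epochs)) {
      losses <- numeric(0)
      buckets <- shuffle(unique(train$n_steps))
      for (Tn in buckets) {
        idx <- shuffle(which(train$n_steps == Tn))
        starts <- seq(1, length(idx), by = spec$batch_size)
        for (s in starts) {
          bidx <- idx[s:min(s + spec$batch_size - 1, length(idx))]
          xs <- apply_input_scaling(stack_batch(train$input[bidx]),
                                    scaling)
          y <- y_all[bidx]
          fw <- seq_forward(spec$family, p, xs)
          losses <- c(losses, seq_loss(fw$prob, y))
          g <- seq_backward(spec$family, p, xs, fw, y)
          g <- g[names(p)] # align component order with the parameter tree
          step <- step + 1L
          m <- tree_map(function(mm, gg) b1 * mm + (1 - b1) * gg, m, g)
          v <- tree_map(function(vv, gg) b2 * vv + (1 - b2) * gg^2, v, g)
          lr_t <- spec$learn_rate *
            sqrt(1 - b2^step) / (1 - b1^step)
          p <- tree_map(function(pp, mm, vv) {
            pp - lr_t * mm / (sqrt(vv) + 1e-8)
          }, p, m, v)
        }
      }
      val_acc <- mean((batch_scores(spec$family, p, val, scaling) >= 0.5) ==
                        y_val)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = mean(losses), val_accuracy = val_acc
      )
      if (val_acc > best$acc) {
        best <- list(acc = val_acc, epoch = epoch, params = p)
      }
    }

    structure(
      list(params = best$params, family = spec$family, spec = spec, d = d,
           scaling = scaling,
           best_epoch = best$epoch, best_val_accuracy = best$acc,
           history = dplyr::bind_rows(history)),
      class = "fld_seq_model"
    )
  })
}

#' @export
print.fld_seq_model <- function(x, ...) {
  cat(sprintf(
    "<fld_seq_model> %s (hidden %d, width %d); best epoch %d (val acc %.4f)\n",
    x$family, x$spec$hidden, x$d, x$best_epoch, x$best_val_accuracy
  ))
  invisible(x)
}

#' Predict next-visit FLD risk for sequence samples
#'
#' @param object An `fld_seq_model`.
#' @param samples An `fld_samples` tibble matching the model's step width.
#' @param ... Unused.
#' @return A tibble with one row per sample: `score` (probability of FLD)
#'   and `label` (`score >= 0.5` is FLD). Deterministic: the same model and
#'   samples always give identical scores.
#' @export
predict.fld_seq_model <- function(object, samples, ...) {
  if (nrow(samples) == 0) {
    return(tibble::tibble(score = numeric(0),
                          label = factor(character(0), levels = FLD_LEVELS)))
  }
  if (sample_width(samples) != object$d) {
    abort(sprintf("samples have step width %d but the model expects %d",
                  sample_width(samples), object$d))
  }
  score <- batch_scores(object$family, object$params, samples,
                        object$scaling)
  tibble::tibble(score = score, label = as_fld_factor(score >= 0.5))
}

#' @export
tidy.fld_seq_model <- function(x, ...) x$history

#' @export
glance.fld_seq_model <- function(x, ...) {
  tibble::tibble(
    family = x$family, hidden = x$spec$hidden, epochs = x$spec$epochs,
    best_epoch = x$best_epoch, best_val_accuracy = x$best_val_accuracy,
    step_width = x$d
  )
}
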