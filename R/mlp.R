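# Multilayer perceptron with ReLU hidden layers, softmax output head(s),
# inverted dropout, Adam, and early stopping on a validation split. Written
# in plain matrix code: the problem sizes here (hundreds of samples, at most
# a few hundred features) never justify a heavier engine. One network can
# carry several softmax heads sharing the hidden trunk, which is how the
# six-trait multi-output model is fitted: per-head cross-entropies are summed
# unweighted.

relu <- function(z) pmax(z, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

one_hot <- function(f) {
  m <- matrix(0, length(f), nlevels(f), dimnames = list(NULL, levels(f)))
  m[cbind(seq_along(f), as.integer(f))] <- 1
  m
}

mlp_init <- function(p, hidden, head_sizes, rng_ok = TRUE) {
  sizes <- c(p, hidden)
  trunk <- purrr::map(seq_along(hidden), function(l) {
    list(
      W = matrix(
        rnorm(sizes[l] * sizes[l + 1], 0, sqrt(2 / sizes[l])), # He init
        sizes[l], sizes[l + 1]
      ),
      b = rep(0, sizes[l + 1])
    )
  })
  last <- sizes[length(sizes)]
  heads <- purrr::map(head_sizes, function(k) {
    list(
      W = matrix(rnorm(last * k, 0, sqrt(2 / last)), last, k),
      b = rep(0, k)
    )
  })
  list(trunk = trunk, heads = heads)
}

mlp_forward <- function(params, x, dropout = 0, train = FALSE) {
  acts <- list(x)
  h <- x
  masks <- list()
  for (l in seq_along(params$trunk)) {
    z <- sweep(h %*% params$trunk[[l]]$W, 2, params$trunk[[l]]$b, `+`)
    h <- relu(z)
    if (train && dropout > 0) {
      mask <- matrix(
        (runif(length(h)) > dropout) / (1 - dropout),
        nrow(h), ncol(h)
      )
      h <- h * mask
      masks[[l]] <- mask
    }
    acts[[l + 1]] <- h
  }
  probs <- purrr::map(params$heads, function(head) {
    softmax_rows(sweep(h %*% head$W, 2, head$b, `+`))
  })
  list(acts = acts, probs = probs, masks = masks)
}

mlp_loss <- function(probs, targets) {
  # summed per-head mean cross-entropy
  sum(purrr::map2_dbl(probs, targets, function(p, t) {
    -mean(log(pmax(rowSums(p * t), 1e-12)))
  }))
}

mlp_gradients <- function(params, fwd, targets) {
  n <- nrow(fwd$acts[[1]])
  n_layers <- length(params$trunk)
  h_last <- fwd$acts[[n_layers + 1]]
  grad_heads <- vector("list", length(params$heads))
  delta_trunk <- 0
  for (j in seq_along(params$heads)) {
    dlogits <- (fwd$probs[[j]] - targets[[j]]) / n
    grad_heads[[j]] <- list(
      W = crossprod(h_last, dlogits),
      b = colSums(dlogits)
    )
    delta_trunk <- delta_trunk + dlogits %*% t(params$heads[[j]]$W)
  }
  grad_trunk <- vector("list", n_layers)
  delta <- delta_trunk
  for (l in rev(seq_len(n_layers))) {
    if (length(fwd$masks) >= l && !is.null(fwd$masks[[l]])) {
      delta <- delta * fwd$masks[[l]]
    }
    delta <- delta * (fwd$acts[[l + 1]] > 0) # ReLU gate
    grad_trunk[[l]] <- list(
      W = crossprod(fwd$acts[[l]], delta),
      b = colSums(delta)
    )
    if (l > 1L) delta <- delta %*% t(params$trunk[[l]]$W)
  }
  list(trunk = grad_trunk, heads = grad_heads)
}

adam_state <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

adam_update <- function(params, grads, state, lr, t, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  walk_update <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  for (part in c("trunk", "heads")) {
    for (l in seq_along(params[[part]])) {
      for (nm in c("W", "b")) {
        u <- walk_update(
          params[[part]][[l]][[nm]], grads[[part]][[l]][[nm]],
          state$m[[part]][[l]][[nm]], state$v[[part]][[l]][[nm]]
        )
        params[[part]][[l]][[nm]] <- u$p
        state$m[[part]][[l]][[nm]] <- u$m
        state$v[[part]][[l]][[nm]] <- u$v
      }
    }
  }
  list(params = params, state = state)
}

as_target_list <- function(y) {
  if (is.factor(y)) {
    list(y)
  } else if (is.data.frame(y)) {
    purrr::map(y, function(col) {
      if (!is.factor(col)) abort("every output column must be a factor")
      col
    })
  } else if (is.list(y)) {
    y
  } else {
    abort("y must be a factor, a list of factors, or a data frame of factors")
  }
}

#' Fit a multilayer perceptron classifier
#'
#' ReLU hidden layers, one softmax head per categorical output, inverted
#' dropout on the hidden activations, Adam optimization of the summed
#' cross-entropy, and early stopping on validation loss (best weights are
#' restored). Inputs are standardized internally.
#'
#' @param x Numeric matrix (samples x features).
#' @param y A factor (single output) or a data frame / list of factors
#'   (multi-output; one softmax head each).
#' @param hidden Integer vector of hidden layer widths.
#' @param dropout Dropout rate on hidden activations during training.
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param x_val,y_val Optional validation split for early stopping.
#' @param patience Epochs without validation improvement before stopping.
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @return An object of class `mlp_model`.
#' @export
mlp_fit <- function(x, y, hidden = c(64, 32), dropout = 0.3, epochs = 200,
                    batch_size = 32, lr = 1e-3, x_val = NULL, y_val = NULL,
                    patience = 20, seed = 1L) {
  targets <- as_target_list(y)
  head_levels <- purrr::map(targets, levels)
  x <- as.matrix(x)
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, `/`)
  t_onehot <- purrr::map(targets, one_hot)

  has_val <- !is.null(x_val) && !is.null(y_val) && nrow(as.matrix(x_val)) > 0L
  if (has_val) {
    vt <- as_target_list(y_val)
    vt <- purrr::map2(vt, head_levels, ~ factor(.x, levels = .y))
    xv <- sweep(sweep(as.matrix(x_val), 2, center), 2, scale, `/`)
    v_onehot <- purrr::map(vt, one_hot)
  }

  withr::with_seed(seed, {
    params <- mlp_init(ncol(xs), hidden, purrr::map_int(t_onehot, ncol))
    state <- list(m = adam_state(params), v = adam_state(params))
    best <- list(loss = Inf, params = params, epoch = 0L)
    stale <- 0L
    t_step <- 0L
    n <- nrow(xs)
    for (epoch in seq_len(epochs)) {
      idx <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        batch <- idx[start:min(start + batch_size - 1L, n)]
        fwd <- mlp_forward(params, xs[batch, , drop = FALSE],
          dropout = dropout, train = TRUE
        )
        grads <- mlp_gradients(
          params, fwd,
          purrr::map(t_onehot, ~ .x[batch, , drop = FALSE])
        )
        t_step <- t_step + 1L
        upd <- adam_update(params, grads, state, lr, t_step)
        params <- upd$params
        state <- upd$state
      }
      if (has_val) {
        vloss <- mlp_loss(mlp_forward(params, xv)$probs, v_onehot)
        if (vloss < best$loss - 1e-6) {
          best <- list(loss = vloss, params = params, epoch = epoch)
          stale <- 0L
        } else {
          stale <- stale + 1L
          if (stale >= patience) break
        }
      }
    }
    if (has_val && is.finite(best$loss)) params <- best$params
  })

  structure(
    list(
      params = params, center = center, scale = scale,
      head_levels = head_levels, hidden = hidden, dropout = dropout,
      multi = length(head_levels) > 1L,
      head_names = names(targets),
      best_epoch = if (has_val) best$epoch else NA_integer_
    ),
    class = "mlp_model"
  )
}

#' Predict from a fitted MLP
#'
#' @param object An [mlp_fit()] model.
#' @param newdata Numeric matrix of features.
#' @param type `"class"` for factor predictions, `"prob"` for per-head
#'   probability matrices.
#' @param ... Unused.
#' @return For a single-head model a factor (or probability matrix); for a
#'   multi-head model a named list with one element per output.
#' @export
predict.mlp_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  xs <- sweep(sweep(as.matrix(newdata), 2, object$center), 2, object$scale, `/`)
  probs <- mlp_forward(object$params, xs)$probs
  out <- purrr::map2(probs, object$head_levels, function(p, lev) {
    colnames(p) <- lev
    if (type == "prob") {
      p
    } else {
      factor(lev[max.col(p, ties.method = "first")], levels = lev)
    }
  })
  names(out) <- object$head_names
  if (!object$multi) out[[1]] else out
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf(
    "<mlp_model> hidden [%s], dropout %.2f, %d output head(s)\n",
    paste(x$hidden, collapse = ", "), x$dropout, length(x$head_levels)
  ))
  invisible(x)
}
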