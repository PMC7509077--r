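#' Training configuration
#'
#' Defaults follow the reference protocol: the Adam optimizer with a ladder
#' of decaying learning rates (1e-4, 5e-5, 2.5e-5, 1e-5), each rate advanced
#' after three consecutive epochs without a decrease of the validation loss,
#' stopping when a decay past the last rate is triggered; Xavier
#' initialization; batch size 32; softmax cross-entropy loss.
#'
#' @param learning_rates strictly decreasing vector of Adam learning rates.
#' @param patience consecutive non-improving epochs before a decay (>= 1).
#' @param batch_size minibatch size.
#' @param max_epochs hard cap on epochs.
#' @param inner_folds folds of the inner cross-validation that fixes epoch
#'   budgets.
#' @param online_augment apply online flip/translate augmentation to each
#'   training draw.
#' @param epoch_budget optional integer vector, one entry per learning rate:
#'   train exactly this many epochs per rate with no validation set (the
#'   retraining mode after inner CV).
#' @param class_weights optional numeric length-2 vector weighting the loss
#'   of (rim-, rim+) samples via oversampling-free reweighting of the
#'   sampling probabilities; NULL for uniform shuffling.
#' @return A \code{train_config} list.
#' @export
train_config <- function(learning_rates = c(1e-4, 5e-5, 2.5e-5, 1e-5),
                         patience = 3L, batch_size = 32L, max_epochs = 60L,
                         inner_folds = 3L, online_augment = TRUE,
                         epoch_budget = NULL, class_weights = NULL) {
  if (any(diff(learning_rates) >= 0))
    stop("learning_rates must be strictly decreasing")
  if (patience < 1L) stop("patience must be >= 1")
  if (!is.null(epoch_budget) && length(epoch_budget) != length(learning_rates))
    stop("epoch_budget needs one entry per learning rate")
  structure(list(learning_rates = learning_rates,
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 inner_folds = as.integer(inner_folds),
                 online_augment = isTRUE(online_augment),
                 epoch_budget = epoch_budget,
                 class_weights = class_weights),
            class = "train_config")
}

#' Learning-rate ladder with early stopping
#'
#' State machine over per-epoch validation losses: an epoch improves when its
#' loss is strictly below the best seen so far; after \code{patience}
#' consecutive non-improving epochs the next (lower) rate is activated and
#' the counter resets; a decay triggered past the last rate stops training.
#'
#' @param rates decreasing learning rates.
#' @param patience consecutive non-improving epochs per decay.
#' @param baseline optional initial best loss (default \code{Inf}; supply a
#'   pre-training validation loss to count the first epoch against it).
#' @return A scheduler state list (fields \code{rate}, \code{rate_index},
#'   \code{stopped}, \code{epoch}, \code{epochs_per_rate}).
#' @export
lr_scheduler <- function(rates, patience = 3L, baseline = Inf) {
  stopifnot(length(rates) >= 1L, patience >= 1L)
  list(rates = rates, patience = as.integer(patience), rate_index = 1L,
       rate = rates[1], best = baseline, bad_epochs = 0L, epoch = 0L,
       stopped = FALSE, decay_epochs = integer(0),
       epochs_per_rate = integer(length(rates)))
}

#' Advance the scheduler by one epoch of validation loss
#'
#' @param state scheduler state from \code{lr_scheduler}.
#' @param val_loss the epoch's validation loss.
#' @return Updated state; \code{state$stopped} turns TRUE at the decay that
#'   would pass the last rate.
#' @export
scheduler_step <- function(state, val_loss) {
  if (state$stopped) stop("scheduler already stopped")
  state$epoch <- state$epoch + 1L
  state$epochs_per_rate[state$rate_index] <-
    state$epochs_per_rate[state$rate_index] + 1L
  if (val_loss < state$best) {
    state$best <- val_loss
    state$bad_epochs <- 0L
  } else {
    state$bad_epochs <- state$bad_epochs + 1L
    if (state$bad_epochs >= state$patience) {
      state$decay_epochs <- c(state$decay_epochs, state$epoch)
      state$bad_epochs <- 0L
      if (state$rate_index == length(state$rates)) {
        state$stopped <- TRUE
      } else {
        state$rate_index <- state$rate_index + 1L
        state$rate <- state$rates[state$rate_index]
      }
    }
  }
  state
}

#' Patient-grouped, per-site stratified fold assignment
#'
#' All lesions of one patient share that patient's fold. Within each site,
#' patients are assigned greedily (largest rim+ load first) to the currently
#' least-loaded fold, so per-fold class counts are balanced per site.
#' Assignment is deterministic given the seed, which only shuffles the order
#' of exact ties.
#'
#' @param patients data frame with columns \code{patient_id},
#'   \code{site_id}, \code{n_rim_pos}, \code{n_rim_neg}.
#' @param n_folds number of folds (default 4).
#' @param seed tie-shuffling seed.
#' @return A \code{fold_split}: data frame mapping \code{patient_id} to
#'   \code{fold}, plus a per-fold, per-site summary in
#'   \code{attr(, "summary")}.
#' @export
make_folds <- function(patients, n_folds = 4L, seed = 1L) {
  req <- c("patient_id", "site_id", "n_rim_pos", "n_rim_neg")
  if (!all(req %in% names(patients))) stop("patients must have columns ",
                                           paste(req, collapse = ", "))
  if (anyDuplicated(patients$patient_id)) stop("duplicate patient_id")
  for (s in unique(patients$site_id)) {
    if (sum(patients$site_id == s) < n_folds)
      stop(sprintf("site %s has fewer patients than folds", s))
  }
  assignment <- NULL
  with_seed(seed, {
    for (s in unique(patients$site_id)) {
      ps <- patients[patients$site_id == s, , drop = FALSE]
      ps <- ps[sample.int(nrow(ps)), , drop = FALSE]  # randomize tie order
      ps <- ps[order(-ps$n_rim_pos, -ps$n_rim_neg), , drop = FALSE]
      load_pos <- numeric(n_folds)
      load_neg <- numeric(n_folds)
      load_n <- integer(n_folds)
      for (i in seq_len(nrow(ps))) {
        ord <- order(load_pos, load_neg, load_n, seq_len(n_folds))
        f <- ord[1]
        load_pos[f] <- load_pos[f] + ps$n_rim_pos[i]
        load_neg[f] <- load_neg[f] + ps$n_rim_neg[i]
        load_n[f] <- load_n[f] + 1L
        assignment <- rbind(assignment,
                            data.frame(patient_id = ps$patient_id[i],
                                       site_id = s, fold = f,
                                       stringsAsFactors = FALSE))
      }
    }
  })
  assignment <- assignment[order(assignment$patient_id), , drop = FALSE]
  rownames(assignment) <- NULL
  merged <- merge(assignment, patients, by = c("patient_id", "site_id"))
  summ <- aggregate(cbind(n_rim_pos, n_rim_neg) ~ fold + site_id, data = merged,
                    FUN = sum)
  attr(assignment, "summary") <- summ
  class(assignment) <- c("fold_split", "data.frame")
  assignment
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

eval_loss <- function(spec, params, running, x, y, batch_size = 64L) {
  n <- length(y)
  per <- length(x) / n
  total <- 0
  probs <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    r <- cnn_batch_cpp(spec, params, running,
                       x[((i - 1) * per + 1):(j * per)], y[i:j],
                       FALSE, FALSE, 0.1, 1e-5)
    total <- total + r$loss * (j - i + 1L)
    probs[i:j] <- r$probs[, 2]
    i <- j + 1L
  }
  list(loss = total / n, probs = probs)
}

#' Train a classification network
#'
#' Adam with the learning-rate ladder: training runs at the first rate until
#' \code{patience} consecutive epochs without validation-loss improvement,
#' then advances down the ladder; the decay that would pass the last rate
#' stops training (early stopping). When \code{config$epoch_budget} is set
#' (retraining mode after inner cross-validation), exactly that many epochs
#' are trained per rate and no validation set is needed.
#'
#' @param x training input array (P, P, P, modalities, N) or a list of
#'   patches.
#' @param y integer labels (1 = rim+, 0 = rim-).
#' @param net a \code{prl_net_spec}.
#' @param config a \code{train_config}.
#' @param val_x,val_y validation set (required unless \code{epoch_budget}).
#' @param seed seed controlling initialization, shuffling and online
#'   augmentation.
#' @param verbose print per-epoch losses.
#' @return A \code{prl_model} with a \code{history} data frame (epoch,
#'   learning rate, training loss, validation loss) and the scheduler state.
#' @export
train_model <- function(x, y, net, config = train_config(), val_x = NULL,
                        val_y = NULL, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(net, "prl_net_spec"), inherits(config, "train_config"))
  if (is.list(x) && !is.array(x)) {
    y <- patch_labels(x)
    x <- patches_to_array(x, net$n_mod)
  }
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes")
  fixed_budget <- !is.null(config$epoch_budget)
  if (!fixed_budget && (is.null(val_x) || is.null(val_y)))
    stop("a validation set is required unless epoch_budget is fixed")
  if (!is.null(val_x) && is.list(val_x) && !is.array(val_x)) {
    val_y <- patch_labels(val_x)
    val_x <- patches_to_array(val_x, net$n_mod)
  }

  P <- net$patch_size
  per <- P^3 * net$n_mod
  n <- length(y)
  xv <- as.double(x)
  spec <- cpp_spec(net)
  model <- init_network(net, seed = derive_seed(seed, "init"))
  params <- model$params
  running <- model$running
  opt <- adam_init(params)
  sched <- lr_scheduler(config$learning_rates, config$patience)
  budget_idx <- 1L
  budget_used <- 0L
  history <- NULL
  aug_cfg <- augment_config(patch_size = P,
                            translate_vox = min(2L, max(1L, P %/% 8L)))

  with_seed(derive_seed(seed, "loop"), {
    for (epoch in seq_len(config$max_epochs)) {
      lr <- if (fixed_budget) config$learning_rates[budget_idx] else sched$rate
      ord <- sample.int(n)
      epoch_loss <- 0
      nb <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        xb <- numeric(length(idx) * per)
        for (k in seq_along(idx)) {
          src <- xv[((idx[k] - 1) * per + 1):(idx[k] * per)]
          if (config$online_augment) {
            pat <- list(data = array(src, c(P, P, P, net$n_mod)),
                        transforms = character(0))
            class(pat) <- "lesion_patch"
            pat <- online_augment(pat, aug_cfg)
            src <- as.double(pat$data)
          }
          xb[((k - 1) * per + 1):(k * per)] <- src
        }
        r <- cnn_batch_cpp(spec, params, running, xb, y[idx], TRUE, TRUE,
                           0.1, 1e-5)
        if (!is.finite(r$loss))
          stop(sprintf("training diverged (loss %s) at epoch %d", r$loss, epoch))
        running <- r$running
        st <- adam_step(params, r$grads, opt, lr)
        params <- st$params
        opt <- st$state
        epoch_loss <- epoch_loss + r$loss
        nb <- nb + 1L
      }
      train_loss <- epoch_loss / nb
      val_loss <- NA_real_
      if (!is.null(val_x)) {
        val_loss <- eval_loss(spec, params, running, as.double(val_x),
                              as.integer(val_y))$loss
      }
      history <- rbind(history, data.frame(epoch = epoch, lr = lr,
                                           train_loss = train_loss,
                                           val_loss = val_loss))
      if (verbose)
        message(sprintf("epoch %3d lr %.2e train %.4f val %s", epoch, lr,
                        train_loss,
                        ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss))))
      if (fixed_budget) {
        budget_used <- budget_used + 1L
        if (budget_used >= config$epoch_budget[budget_idx]) {
          budget_idx <- budget_idx + 1L
          budget_used <- 0L
          while (budget_idx <= length(config$epoch_budget) &&
                 config$epoch_budget[budget_idx] == 0L)
            budget_idx <- budget_idx + 1L
          if (budget_idx > length(config$epoch_budget)) break
        }
      } else {
        sched <- scheduler_step(sched, val_loss)
        if (sched$stopped) break
      }
    }
  })

  structure(list(spec = net, params = params, running = running,
                 history = history, scheduler = sched, config = config,
                 seed = seed),
            class = "prl_model")
}

#' Determine per-rate epoch budgets by inner cross-validation
#'
#' Splits the training patients into \code{inner_folds} groups, trains with
#' the full ladder + early-stopping protocol on each inner split, and
#' averages (rounding half up) the number of epochs spent at each learning
#' rate. The budgets are then used to retrain on the full outer-training set
#' without a validation set.
#'
#' @param x input array; @param y labels; @param groups patient ids
#'   (grouping unit of the inner split).
#' @param net a \code{prl_net_spec}; @param config a \code{train_config};
#'   @param seed seed.
#' @return Integer vector of epochs per learning rate.
#' @export
inner_cv_epochs <- function(x, y, groups, net, config = train_config(),
                            seed = 1L) {
  y <- as.integer(y)
  ug <- unique(groups)
  if (length(ug) < config$inner_folds) stop("not enough patients for inner CV")
  fold_of <- with_seed(derive_seed(seed, "innercv"), {
    setNames(rep_len(sample.int(config$inner_folds), length(ug)),
             sample(ug))
  })
  per_rate <- matrix(0L, config$inner_folds, length(config$learning_rates))
  for (f in seq_len(config$inner_folds)) {
    te <- groups %in% names(fold_of)[fold_of == f]
    if (length(unique(y[!te])) < 2L || length(unique(y[te])) < 2L)
      stop(sprintf("inner fold %d lacks a class", f))
    m <- train_model(index_input(x, !te, net), y[!te], net, config,
                     val_x = index_input(x, te, net), val_y = y[te],
                     seed = derive_seed(seed, paste0("inner", f)))
    per_rate[f, ] <- m$scheduler$epochs_per_rate
  }
  budget <- as.integer(round_half_up(colMeans(per_rate)))
  pmax(budget, c(1L, rep(0L, length(budget) - 1L)))
}

index_input <- function(x, keep, net) {
  d <- dim(x)
  x[, , , , which(keep), drop = FALSE]
}

#' Ensemble prediction by probability averaging
#'
#' @param models list of \code{prl_model} with identical architectures.
#' @param x input array or patch list.
#' @return Mean per-input rim+ probability across models.
#' @export
ensemble_predict <- function(models, x) {
  if (length(models) == 0L) stop("at least one model is required")
  ref <- models[[1]]$spec
  for (m in models) {
    if (!identical(m$spec[c("n_mod", "patch_size", "filters", "fc")],
                   ref[c("n_mod", "patch_size", "filters", "fc")]))
      stop("ensemble members must share one architecture")
  }
  probs <- vapply(models, function(m) predict_proba(m, x),
                  numeric(if (is.array(x)) dim(x)[5] else length(x)))
  rowMeans(as.matrix(probs))
}
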