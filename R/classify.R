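#' Classifier specification
#'
#' Describes one of the three classifier families and the topology used to
#' obtain ground-truth accuracy: `single` (one multiclass machine), `ovo`
#' (all pairwise binary machines with majority voting), `ami` ("all
#' movements as individual", the label power set — every movement
#' combination is its own class, mechanically identical to `single` over
#' the combined labels), and `mix` (one binary output per individual
#' movement; simultaneous movements activate several outputs).
#'
#' @param family `"lda"`, `"mlp"` or `"svm"`.
#' @param topology `"single"`, `"ovo"`, `"ami"` or `"mix"`.
#' @param hidden_units MLP hidden layer size; default `NULL` means
#'   `max(10, number of outputs)`.
#' @param max_epochs MLP training iterations (default 200).
#' @param decay_grid MLP weight-decay grid searched on the validation set
#'   (the validation data controls capacity).
#' @param kernel_degree SVM polynomial kernel degree (default 2, a
#'   quadratic kernel).
#' @param cost SVM regularization constant (default 1).
#' @param seed integer seed controlling any stochastic training.
#' @return a `classifier_spec` list.
#' @export
classifier_spec <- function(family = c("lda", "mlp", "svm"),
                            topology = c("single", "ovo", "ami", "mix"),
                            hidden_units = NULL, max_epochs = 200L,
                            decay_grid = c(0, 1e-4, 1e-2),
                            kernel_degree = 2L, cost = 1, seed = 1L) {
  family <- match.arg(family)
  topology <- match.arg(topology)
  if (topology == "mix" && family == "lda") {
    stop("mix topology needs per-output machines (mlp or svm)")
  }
  if (topology == "ovo" && family != "lda") {
    warning("ovo with ", family, " is beyond the usual benchmark usage")
  }
  structure(list(family = family, topology = topology,
                 hidden_units = hidden_units,
                 max_epochs = as.integer(max_epochs),
                 decay_grid = decay_grid,
                 kernel_degree = as.integer(kernel_degree), cost = cost,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Movement label space for simultaneous problems
#'
#' Builds the bijection between combined (label power set, AMI) classes and
#' binary output vectors (MIX) for a set of degrees of freedom, each with a
#' list of mutually exclusive movements plus the implicit inactive state.
#' The all-inactive combination is labeled `rest_label`, and the MIX output
#' space is the union of the individual movements; an all-zero output
#' vector maps to rest.
#'
#' @param dof_movements list of character vectors, one per degree of
#'   freedom, each holding that DoF's mutually exclusive movements (e.g.
#'   `list(c("open", "close"), c("flex", "extend"))`).
#' @param rest_label label of the all-inactive combination (default
#'   `"rest"`).
#' @param sep separator joining simultaneous movements into a combined
#'   label (default `"+"`).
#' @return a `movement_label_space`: list with `ami_labels` (all
#'   realizable combinations), `outputs` (individual movements = MIX output
#'   names) and `mix_matrix` (combinations x outputs binary matrix).
#' @export
movement_label_space <- function(dof_movements, rest_label = "rest",
                                 sep = "+") {
  stopifnot(is.list(dof_movements), length(dof_movements) >= 1L)
  outputs <- unlist(dof_movements, use.names = FALSE)
  if (anyDuplicated(outputs)) stop("movements must be unique across DoFs")
  choices <- lapply(dof_movements, function(m) c(NA_character_, m))
  grid <- expand.grid(choices, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  ami <- apply(grid, 1, function(row) {
    act <- row[!is.na(row)]
    if (!length(act)) rest_label else paste(act, collapse = sep)
  })
  mix <- t(apply(grid, 1, function(row) as.integer(outputs %in% row)))
  colnames(mix) <- outputs
  rownames(mix) <- ami
  structure(list(ami_labels = ami, outputs = outputs, mix_matrix = mix,
                 rest_label = rest_label, sep = sep),
            class = "movement_label_space")
}

#' Map an AMI (combined) label to its MIX binary output vector
#' @param space a [movement_label_space()].
#' @param labels character vector of combined labels.
#' @return labels x outputs binary matrix.
#' @export
ami_to_mix <- function(space, labels) {
  idx <- match(labels, space$ami_labels)
  if (anyNA(idx)) {
    stop("label(s) outside the label space: ",
         paste(unique(labels[is.na(idx)]), collapse = ", "))
  }
  space$mix_matrix[idx, , drop = FALSE]
}

#' Map MIX binary output vectors back to combined labels
#' @param space a [movement_label_space()].
#' @param mix rows x outputs binary matrix (columns ordered as
#'   `space$outputs`).
#' @return character vector of combined labels; all-zero rows map to rest,
#'   unrealizable combinations to `NA`.
#' @export
mix_to_ami <- function(space, mix) {
  mix <- as.matrix(mix)
  key <- apply(space$mix_matrix, 1, paste, collapse = "")
  unname(apply(mix, 1, function(row) {
    i <- match(paste(as.integer(row), collapse = ""), key)
    if (is.na(i)) NA_character_ else space$ami_labels[i]
  }))
}

train_one_machine <- function(spec, X, y, Xval = NULL, yval = NULL) {
  y <- factor(y)
  df <- data.frame(X, check.names = FALSE)
  switch(spec$family,
    lda = MASS::lda(x = X, grouping = y),
    svm = e1071::svm(x = X, y = y, kernel = "polynomial",
                     degree = spec$kernel_degree, coef0 = 1,
                     cost = spec$cost, scale = TRUE),
    mlp = {
      hid <- if (is.null(spec$hidden_units))
        max(10L, nlevels(y)) else spec$hidden_units
      best <- NULL; best_err <- Inf
      for (dec in spec$decay_grid) {
        set.seed(spec$seed)
        net <- nnet::nnet(x = X, y = nnet::class.ind(y), size = hid,
                          decay = dec, maxit = spec$max_epochs,
                          softmax = FALSE, entropy = FALSE, trace = FALSE,
                          MaxNWts = 100000L)
        err <- if (is.null(Xval) || !nrow(Xval)) net$value else {
          p <- predict_one_machine(spec, list(fit = net, levels = levels(y),
                                              family = "mlp"), Xval)
          mean(p != yval)
        }
        if (err < best_err) { best_err <- err; best <- net }
      }
      best
    })
}

predict_one_machine <- function(spec, machine, X) {
  switch(machine$family,
    lda = as.character(stats::predict(machine$fit, X)$class),
    svm = as.character(stats::predict(machine$fit, X)),
    mlp = {
      p <- stats::predict(machine$fit, X)
      machine$levels[max.col(p, ties.method = "first")]
    })
}

machine_scores <- function(machine, X) {
  # per-class scores used for OVO tie-breaks
  switch(machine$family,
    lda = {
      p <- stats::predict(machine$fit, X)$posterior
      p
    },
    svm = attr(stats::predict(machine$fit, X, decision.values = TRUE),
               "decision.values"),
    mlp = stats::predict(machine$fit, X))
}

#' Train a classifier
#'
#' Trains the machine(s) implied by the spec's family and topology.
#' Training is deterministic given `spec$seed`.  The MLP searches its
#' weight-decay grid against the validation set (capacity selection on
#' held-out data); LDA and SVM ignore the validation set.
#'
#' @param spec a [classifier_spec()].
#' @param train a [feature_matrix()] with at least two classes.
#' @param validation a [feature_matrix()]; required for `mlp`.
#' @param label_space a [movement_label_space()]; required for `mix`,
#'   optional otherwise.
#' @return a `trained_classifier` handle.
#' @export
train <- function(spec, train, validation = NULL, label_space = NULL) {
  stopifnot(inherits(spec, "classifier_spec"),
            inherits(train, "feature_matrix"))
  X <- train$values
  y <- train$class
  if (any(!is.finite(X))) stop("NaN/Inf in training features")
  if (length(unique(y)) < 2L) stop("training data has a single class")
  if (spec$family == "mlp" &&
      (is.null(validation) || nrow(validation$values) == 0L)) {
    stop("mlp requires a non-empty validation set")
  }
  Xval <- if (is.null(validation)) NULL else validation$values
  yval <- if (is.null(validation)) NULL else validation$class
  set.seed(spec$seed)
  model <- if (spec$topology == "ovo") {
    pairs <- utils::combn(sort(unique(y)), 2, simplify = FALSE)
    machines <- lapply(pairs, function(pr) {
      sel <- y %in% pr
      list(fit = train_one_machine(spec, X[sel, , drop = FALSE], y[sel],
                                   Xval, yval),
           levels = pr, family = spec$family)
    })
    list(kind = "ovo", machines = machines, pairs = pairs)
  } else if (spec$topology == "mix") {
    if (is.null(label_space)) stop("mix topology requires a label_space")
    targets <- ami_to_mix(label_space, y)
    machines <- lapply(label_space$outputs, function(out) {
      yy <- factor(targets[, out], levels = c(0L, 1L))
      list(fit = train_one_machine(spec, X, yy, Xval,
                                   if (is.null(yval)) NULL else
                                     factor(ami_to_mix(label_space, yval)[, out],
                                            levels = c(0L, 1L))),
           levels = c("0", "1"), family = spec$family)
    })
    names(machines) <- label_space$outputs
    list(kind = "mix", machines = machines)
  } else {                                  # single / ami: one multiclass
    list(kind = "multiclass",
         machine = list(fit = train_one_machine(spec, X, y, Xval, yval),
                        levels = sort(unique(y)), family = spec$family))
  }
  structure(list(spec = spec, model = model, label_space = label_space,
                 classes = sort(unique(y)), d = ncol(X)),
            class = "trained_classifier")
}

#' Predict labels (or MIX output vectors) for new feature rows
#'
#' @param object a `trained_classifier`.
#' @param fm a [feature_matrix()] with the dimensionality seen in
#'   training.
#' @param ... unused.
#' @return for `single`/`ami`/`ovo`: character vector of predicted labels;
#'   for `mix`: rows x outputs binary matrix (real-valued outputs
#'   thresholded at 0.5), plus the decoded combined label in attribute
#'   `"label"`.
#' @export
predict.trained_classifier <- function(object, fm, ...) {
  stopifnot(inherits(fm, "feature_matrix"))
  X <- fm$values
  if (ncol(X) != object$d) {
    stop("dimension mismatch: model expects ", object$d, " columns")
  }
  m <- object$model
  if (m$kind == "multiclass") {
    return(predict_one_machine(object$spec, m$machine, X))
  }
  if (m$kind == "ovo") {
    votes <- matrix(0L, nrow(X), length(object$classes),
                    dimnames = list(NULL, object$classes))
    score <- matrix(0, nrow(X), length(object$classes),
                    dimnames = list(NULL, object$classes))
    for (mach in m$machines) {
      pred <- predict_one_machine(object$spec, mach, X)
      for (cl in mach$levels) {
        votes[, cl] <- votes[, cl] + (pred == cl)
      }
      if (mach$family == "lda") {
        sc <- machine_scores(mach, X)
        score[, colnames(sc)] <- score[, colnames(sc)] + sc
      }
    }
    # majority vote; ties broken by summed discriminant scores
    return(vapply(seq_len(nrow(X)), function(i) {
      top <- which(votes[i, ] == max(votes[i, ]))
      if (length(top) > 1L) top <- top[which.max(score[i, top])]
      object$classes[top]
    }, ""))
  }
  # mix: one binary machine per output, thresholded at 0.5
  out <- matrix(0L, nrow(X), length(m$machines),
                dimnames = list(NULL, names(m$machines)))
  for (nm in names(m$machines)) {
    mach <- m$machines[[nm]]
    if (mach$family == "mlp") {
      p <- stats::predict(mach$fit, X)
      out[, nm] <- as.integer(p[, ncol(p)] >= 0.5)
    } else {
      out[, nm] <- as.integer(predict_one_machine(object$spec, mach, X) == "1")
    }
  }
  attr(out, "label") <- if (is.null(object$label_space)) NULL else
    mix_to_ami(object$label_space, out)
  out
}

#' Classification accuracy report
#'
#' Overall accuracy is the fraction of correctly classified test windows.
#' For the `mix` topology a window counts as correct only when the full
#' binary output vector matches exactly.  Per-movement accuracies weighted
#' by movement prevalence average to the overall value.
#'
#' @param model a `trained_classifier`.
#' @param test a non-empty [feature_matrix()].
#' @return an `accuracy_report`: list with `overall`, `per_movement`,
#'   `confusion` (true x predicted counts) and `n`.
#' @export
accuracy <- function(model, test) {
  stopifnot(inherits(model, "trained_classifier"),
            inherits(test, "feature_matrix"))
  if (nrow(test$values) == 0L) stop("empty test set")
  truth <- test$class
  if (model$model$kind == "mix") {
    pred_mat <- predict(model, test)
    truth_mat <- ami_to_mix(model$label_space, truth)
    ok <- rowSums(pred_mat != truth_mat) == 0L
    pred_lab <- attr(pred_mat, "label")
    pred_lab[is.na(pred_lab)] <- "<unrealizable>"
  } else {
    pred_lab <- predict(model, test)
    ok <- pred_lab == truth
  }
  per <- vapply(unique(truth), function(cl) mean(ok[truth == cl]), 0)
  names(per) <- unique(truth)
  structure(list(overall = mean(ok), per_movement = per,
                 confusion = table(truth = truth, predicted = pred_lab),
                 n = length(truth)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("accuracy: %.4f over %d test windows\n", x$overall, x$n))
  for (nm in names(x$per_movement)) {
    cat(sprintf("  %-16s %.4f\n", nm, x$per_movement[[nm]]))
  }
  invisible(x)
}
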