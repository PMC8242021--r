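#' DP-compatibility model surgery
#'
#' Per-sample gradient semantics require every layer's output for sample i
#' to be a function of sample i alone. Layers that accumulate statistics
#' across samples or batches break this — chiefly batch normalisation with
#' running statistics, which additionally leaks (non-private) information
#' about past batches through its buffers. `scan_model()` detects such
#' layers, `fix_model()` repairs them, and `validate_model()` is the gate
#' [wrap_model()] calls before allowing per-sample training.
#'
#' The default repair disables the collection of running statistics: the
#' layer computes with current statistics in training and evaluation
#' alike, its learnable affine parameters untouched. In the per-sample
#' execution regime "current statistics" means single-sample (per-channel,
#' spatial) statistics — the batch-size-1 convention this package adopts
#' and documents, since statistics-free batch-norm at batch size one is
#' otherwise undefined. The opt-in alternative `strategy = "group_norm"`
#' substitutes a group-normalisation layer reusing the same gamma/beta.
#'
#' @param model a [dp_model()].
#' @return `scan_model()`: a `surgery_report` — data frame of findings
#'   (`layer`, `issue`, `action`) plus a `compliant` flag. `fix_model()`:
#'   list with the repaired `model` and the `report` of actions taken.
#'   `validate_model()`: the model, invisibly, or an error naming the
#'   offending layers.
#' @examples
#' set.seed(1)
#' m <- dp_model(layer_conv2d(1, 2), layer_batch_norm2d(2), layer_relu())
#' scan_model(m)$compliant        # FALSE
#' m2 <- fix_model(m)$model
#' scan_model(m2)$compliant       # TRUE
#' @export
scan_model <- function(model) {
  stopifnot(inherits(model, "dp_model"))
  known <- c("dense", "relu", "sigmoid", "flatten", "conv2d", "avgpool2d",
             "batch_norm2d", "group_norm")
  findings <- list()
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (!(l$type %in% known)) {
      findings[[length(findings) + 1]] <- data.frame(
        layer = layer_id(i), issue = paste0("unknown layer kind '", l$type, "'"),
        action = "action required: cannot certify per-sample purity")
    } else if (l$type == "batch_norm2d" && l$track_running_stats) {
      findings[[length(findings) + 1]] <- data.frame(
        layer = layer_id(i),
        issue = "batch-norm running statistics accumulate non-private cross-batch state",
        action = "action required: disable running statistics (fix_model)")
    }
  }
  findings <- if (length(findings)) do.call(rbind, findings)
              else data.frame(layer = character(0), issue = character(0),
                              action = character(0))
  structure(list(findings = findings, compliant = nrow(findings) == 0),
            class = "surgery_report")
}

#' @export
print.surgery_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.surgery_report <- function(x, ...) {
  head <- sprintf("surgery report: %s (%d finding%s)",
                  if (x$compliant) "compliant" else "NOT compliant",
                  nrow(x$findings), if (nrow(x$findings) == 1) "" else "s")
  if (nrow(x$findings) == 0) return(head)
  c(head, sprintf("  %s: %s -> %s", x$findings$layer, x$findings$issue,
                  x$findings$action))
}

#' @rdname scan_model
#' @param strategy `"disable_stats"` (default): switch flagged batch-norm
#'   layers to statistics-free operation; `"group_norm"`: replace them with
#'   group normalisation (same affine parameters).
#' @param groups group count for the `"group_norm"` strategy (must divide
#'   the channel count; defaults to the largest of 4/2/1 that does).
#' @export
fix_model <- function(model, strategy = c("disable_stats", "group_norm"),
                      groups = NULL) {
  stopifnot(inherits(model, "dp_model"))
  strategy <- match.arg(strategy)
  pre <- scan_model(model)
  unknown <- grepl("unknown layer kind", pre$findings$issue)
  if (any(unknown)) {
    stop("dp-incompatibility: cannot repair layers of unknown kind: ",
         paste(pre$findings$layer[unknown], collapse = ", "), call. = FALSE)
  }
  actions <- pre$findings
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$type == "batch_norm2d" && l$track_running_stats) {
      id <- layer_id(i)
      if (strategy == "disable_stats") {
        l$track_running_stats <- FALSE
        actions$action[actions$layer == id] <-
          "running statistics disabled; current-sample statistics in all modes"
      } else {
        G <- groups %||% Find(function(g) l$channels %% g == 0, c(4L, 2L, 1L))
        if (l$channels %% G != 0)
          stop("groups must divide channels", call. = FALSE)
        l <- layer_group_norm(l$channels, G)
        actions$action[actions$layer == id] <-
          sprintf("replaced by group_norm (G=%d), affine parameters reused", G)
      }
      model$layers[[i]] <- l
      # running buffers are dead state after the repair
      for (buf in c(".running_mean", ".running_var")) {
        nm <- paste0(id, buf)
        if (exists(nm, envir = model$buffers)) rm(list = nm, envir = model$buffers)
      }
    }
  }
  report <- structure(list(findings = actions, compliant = TRUE),
                      class = "surgery_report")
  list(model = model, report = report)
}

#' @rdname scan_model
#' @export
validate_model <- function(model) {
  rep <- scan_model(model)
  if (!rep$compliant) {
    stop("dp-incompatibility:\n", paste(format(rep), collapse = "\n"),
         call. = FALSE)
  }
  invisible(model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
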