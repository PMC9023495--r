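# Checkpoint format: a directory holding spec.yaml (the architecture),
# params.json (named per-layer parameter tensors with dims), and
# cut_history.json. Plain text throughout; loaders re-validate every
# tensor shape against the spec with the cut history applied.

spec_to_plain <- function(spec) {
  list(layers = lapply(spec$layers, unclass),
       blocks = spec$blocks,
       hidden_dim = spec$hidden_dim, n_classes = spec$n_classes,
       input_size = spec$input_size, in_channels = spec$in_channels)
}

spec_from_plain <- function(pl) {
  layers <- lapply(pl$layers, function(l)
    layer_spec(l$kind, l$out_filters, l$kernel, l$stride, l$has_norm,
               l$activation))
  network_spec(layers, pl$blocks, hidden_dim = pl$hidden_dim,
               n_classes = pl$n_classes, input_size = pl$input_size,
               in_channels = pl$in_channels)
}

#' Save / load model checkpoints
#'
#' @param model a `model_state`.
#' @param dir checkpoint directory (created if missing).
#' @return `save_checkpoint` returns `dir` invisibly; `load_checkpoint`
#'   returns the reconstructed `model_state`.
#' @export
save_checkpoint <- function(model, dir) {
  cn_assert(inherits(model, "model_state"), "input", "model must be a model_state")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(spec_to_plain(model$spec), file.path(dir, "spec.yaml"))
  flat <- lapply(model$params, function(p)
    lapply(p, function(t) list(dim = as.integer(dim(t) %||% length(t)),
                               data = as.vector(t))))
  jsonlite::write_json(flat, file.path(dir, "params.json"),
                       digits = NA, auto_unbox = FALSE)
  jsonlite::write_json(model$cut_history, file.path(dir, "cut_history.json"),
                       auto_unbox = FALSE)
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  cn_assert(file.exists(file.path(dir, "spec.yaml")), "input",
            "no spec.yaml under %s", dir)
  spec <- spec_from_plain(yaml::read_yaml(file.path(dir, "spec.yaml")))
  flat <- jsonlite::read_json(file.path(dir, "params.json"),
                              simplifyVector = FALSE)
  params <- lapply(flat, function(p) lapply(p, function(t) {
    v <- as.numeric(unlist(t$data))
    d <- as.integer(unlist(t$dim))
    if (length(d) > 1) array(v, d) else v
  }))
  ch <- jsonlite::read_json(file.path(dir, "cut_history.json"),
                            simplifyVector = FALSE)
  cut_history <- lapply(ch, function(h)
    list(block = as.integer(unlist(h$block)),
         removed = as.integer(unlist(h$removed))))
  model <- structure(list(spec = spec, params = params,
                          cut_history = cut_history), class = "model_state")
  validate_model_shapes(model)
  model
}

# Replay a cut history against an (original, uncut) spec; reproduces the
# post-cut shapes, which is the invariant tying cut_history to the state.
replay_cut_history <- function(spec, history) {
  for (h in history) spec <- cut_spec(spec, h$block, length(h$removed))
  spec
}

expected_shapes <- function(spec, i) {
  ls <- spec$layers[[i]]
  in_ch <- spec$in_ch[i]
  sh <- list()
  if (ls$kind == "fully_connected") {
    sh$W <- c(ls$out_filters, in_ch); sh$b <- ls$out_filters
  } else if (ls$kind == "depthwise_conv") {
    sh$W <- c(ls$out_filters, ls$kernel, ls$kernel)
  } else {
    sh$W <- c(ls$out_filters, in_ch, ls$kernel, ls$kernel)
  }
  if (ls$kind != "fully_connected") {
    if (ls$has_norm) {
      sh$gamma <- ls$out_filters; sh$beta <- ls$out_filters
      sh$running_mean <- ls$out_filters; sh$running_var <- ls$out_filters
    } else sh$b <- ls$out_filters
  }
  sh
}

validate_model_shapes <- function(model) {
  for (i in seq_along(model$spec$layers)) {
    sh <- expected_shapes(model$spec, i)
    for (nm in names(sh)) {
      t <- model$params[[i]][[nm]]
      cn_assert(!is.null(t), "spec", "layer %d missing tensor %s", i, nm)
      got <- dim(t) %||% length(t)
      cn_assert(identical(as.integer(got), as.integer(sh[[nm]])), "spec",
                "layer %d tensor %s has shape (%s), expected (%s)",
                i, nm, paste(got, collapse = ","),
                paste(sh[[nm]], collapse = ","))
    }
  }
  invisible(TRUE)
}
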