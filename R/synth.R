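#' Configuration for the synthetic glyph-image generator
#'
#' Describes a deterministic multi-class labeled image task. Each class is a
#' fixed parametric prototype: a handful of textured superellipse glyphs with
#' class-specific position, size, shape exponent, hue and stripe pattern,
#' drawn on a smoothly shaded background. Individual images perturb the
#' prototype by a small geometric jitter and additive pixel noise, then
#' quantize to 8-bit RGB. An identical configuration always yields a
#' byte-identical dataset.
#'
#' @param n_classes number of categories (positive integer).
#' @param n_per_class images generated per category.
#' @param image_size side of the square image in pixels.
#' @param noise_sd standard deviation of additive pixel noise, on the [0,1]
#'   intensity scale; must lie in [0,1].
#' @param similarity scalar in [0,1): 0 keeps class prototypes pairwise
#'   distinct, larger values interpolate every prototype toward one shared
#'   template, making classes harder to separate.
#' @param jitter non-negative scale of per-image geometric perturbation
#'   (glyph position/size/color); 0 renders the bare prototype, 1 is the
#'   default realistic setting.
#' @param seed integer seed controlling the per-image noise/jitter stream.
#' @param prototype_seed integer seed base for class prototypes; class k uses
#'   stream `prototype_seed + k - 1`. Defaults to `1000003 * seed`. Source
#'   and target tasks must use disjoint prototype seed ranges.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_classes, n_per_class, image_size = 64,
                         noise_sd = 0.05, similarity = 0, jitter = 1,
                         seed = 1, prototype_seed = NULL) {
  cn_assert(is_count(n_classes), "config", "n_classes must be a positive integer")
  cn_assert(is_count(n_per_class), "config", "n_per_class must be a positive integer")
  cn_assert(is_count(image_size) && image_size >= 8, "config",
            "image_size must be an integer >= 8")
  cn_assert(is.numeric(noise_sd) && noise_sd >= 0 && noise_sd <= 1, "config",
            "noise_sd must lie in [0,1]")
  cn_assert(is.numeric(similarity) && similarity >= 0 && similarity < 1,
            "config", "similarity must lie in [0,1)")
  cn_assert(is.numeric(jitter) && jitter >= 0, "config", "jitter must be >= 0")
  if (is.null(prototype_seed)) prototype_seed <- (1000003 * seed) %% 2147483629
  structure(list(
    n_classes = as.integer(n_classes), n_per_class = as.integer(n_per_class),
    image_size = as.integer(image_size), noise_sd = noise_sd,
    similarity = similarity, jitter = jitter, seed = as.integer(seed),
    prototype_seed = as.integer(prototype_seed)
  ), class = "synth_config")
}

# Continuous prototype parameters for one class, drawn from a dedicated
# stream. Everything is numeric so prototypes can be linearly interpolated
# toward the shared template (the `similarity` control).
draw_proto_params <- function(seedval, n_glyphs = 3L) {
  with_seed(seedval, {
    list(
      bg_rgb = runif(3, 0.15, 0.55),
      bg_angle = runif(1, 0, pi),
      bg_strength = runif(1, 0.05, 0.20),
      bg_freq = runif(1, 1, 4),
      bg_amp = runif(1, 0.03, 0.08),
      glyphs = lapply(seq_len(n_glyphs), function(g) list(
        cx = runif(1, 0.22, 0.78), cy = runif(1, 0.22, 0.78),
        r = runif(1, 0.10, 0.22), p = runif(1, 1.2, 4),
        rgb = runif(3, 0.25, 0.95),
        stripe_freq = runif(1, 0, 7), stripe_angle = runif(1, 0, pi),
        stripe_amp = runif(1, 0, 0.35)
      ))
    )
  })
}

lerp <- function(a, b, s) (1 - s) * a + s * b

blend_params <- function(cls, tmpl, s) {
  if (s == 0) return(cls)
  out <- cls
  for (f in c("bg_rgb", "bg_angle", "bg_strength", "bg_freq", "bg_amp"))
    out[[f]] <- lerp(cls[[f]], tmpl[[f]], s)
  out$glyphs <- Map(function(g, tg) {
    for (f in names(g)) g[[f]] <- lerp(g[[f]], tg[[f]], s)
    g
  }, cls$glyphs, tmpl$glyphs)
  out
}

# Render one (H, W, 3) image in [0,1] from prototype parameters. Uses the
# current RNG stream for jitter when jitter > 0; deterministic otherwise.
render_glyph_image <- function(params, size, jitter = 0) {
  u <- (seq_len(size) - 0.5) / size
  xx <- matrix(u, size, size, byrow = TRUE)   # column coordinate
  yy <- matrix(u, size, size)                 # row coordinate
  proj <- xx * cos(params$bg_angle) + yy * sin(params$bg_angle)
  shade <- params$bg_strength * (proj - 0.5) +
    params$bg_amp * sin(2 * pi * params$bg_freq * proj)
  img <- array(0, c(size, size, 3))
  for (c in 1:3) img[, , c] <- params$bg_rgb[c] + shade
  # per-image framing: a global zoom and offset of the glyph ensemble,
  # emulating varying camera distance and position across photographs
  zoom <- 1; off <- c(0, 0)
  if (jitter > 0) {
    zoom <- exp(rnorm(1, 0, 0.15 * jitter))
    off <- rnorm(2, 0, 0.04 * jitter)
  }
  for (g in params$glyphs) {
    cx <- 0.5 + (g$cx - 0.5) * zoom + off[1]
    cy <- 0.5 + (g$cy - 0.5) * zoom + off[2]
    r <- g$r * zoom
    col <- g$rgb
    if (jitter > 0) {
      cx <- cx + rnorm(1, 0, 0.03 * jitter)
      cy <- cy + rnorm(1, 0, 0.03 * jitter)
      r <- r * exp(rnorm(1, 0, 0.08 * jitter))
      col <- col + rnorm(3, 0, 0.02 * jitter)
    }
    mask <- (abs(xx - cx) / r)^g$p + (abs(yy - cy) / r)^g$p <= 1
    sp <- xx * cos(g$stripe_angle) + yy * sin(g$stripe_angle)
    fac <- 1 + g$stripe_amp * sin(2 * pi * g$stripe_freq * sp)
    for (c in 1:3) {
      plane <- img[, , c]
      plane[mask] <- (col[c] * fac)[mask]
      img[, , c] <- plane
    }
  }
  clamp01(img)
}

class_prototype_params <- function(cfg) {
  tmpl <- draw_proto_params(derive_seed(cfg$prototype_seed, 999983L))
  lapply(seq_len(cfg$n_classes), function(k) {
    cls <- draw_proto_params((cfg$prototype_seed + k - 1L) %% 2147483629)
    blend_params(cls, tmpl, cfg$similarity)
  })
}

#' Noise-free class prototype images
#'
#' @param cfg a [synth_config()].
#' @return list of `n_classes` arrays (H, W, 3) in [0,1], the bare prototype
#'   renders (no jitter, no noise, no quantization).
#' @export
class_prototypes <- function(cfg) {
  cn_assert(inherits(cfg, "synth_config"), "config", "cfg must be a synth_config")
  params <- class_prototype_params(cfg)
  lapply(params, render_glyph_image, size = cfg$image_size, jitter = 0)
}

#' Generate a deterministic labeled image dataset
#'
#' @param cfg a [synth_config()].
#' @return an object of class `labeled_dataset`: a list with `images` (list
#'   of (H, W, 3) arrays in [0,1], quantized to 8-bit steps), `labels`
#'   (0-based integer category ids), `class_names`, and `config`.
#' @export
generate_dataset <- function(cfg) {
  cn_assert(inherits(cfg, "synth_config"), "config", "cfg must be a synth_config")
  params <- class_prototype_params(cfg)
  size <- cfg$image_size
  images <- vector("list", cfg$n_classes * cfg$n_per_class)
  labels <- integer(length(images))
  with_seed(cfg$seed, {
    i <- 0L
    for (k in seq_len(cfg$n_classes)) {
      for (j in seq_len(cfg$n_per_class)) {
        img <- render_glyph_image(params[[k]], size, jitter = cfg$jitter)
        if (cfg$noise_sd > 0)
          img <- clamp01(img + array(rnorm(length(img), 0, cfg$noise_sd), dim(img)))
        i <- i + 1L
        images[[i]] <- round(img * 255) / 255
        labels[i] <- k - 1L
      }
    }
  })
  structure(list(
    images = images, labels = labels,
    class_names = sprintf("class_%03d", seq_len(cfg$n_classes) - 1L),
    config = cfg
  ), class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d images, %d classes, %dx%d px\n",
              length(x$images), length(x$class_names),
              dim(x$images[[1]])[1], dim(x$images[[1]])[2]))
  invisible(x)
}

#' Generate a disjoint source/target task pair
#'
#' The source task stands in for a large generic pre-training corpus: it
#' shares the generator's low-level image statistics with the target task
#' but uses a disjoint set of class prototypes, so features transfer while
#' labels do not.
#'
#' @param source_cfg,target_cfg [synth_config()]s whose prototype seed
#'   ranges must not overlap.
#' @return list with elements `source` and `target`, both `labeled_dataset`s.
#' @export
make_source_target_pair <- function(source_cfg, target_cfg) {
  cn_assert(inherits(source_cfg, "synth_config") &&
              inherits(target_cfg, "synth_config"),
            "config", "both arguments must be synth_configs")
  s_rng <- c(source_cfg$prototype_seed,
             source_cfg$prototype_seed + source_cfg$n_classes - 1L)
  t_rng <- c(target_cfg$prototype_seed,
             target_cfg$prototype_seed + target_cfg$n_classes - 1L)
  if (s_rng[1] <= t_rng[2] && t_rng[1] <= s_rng[2])
    cn_stop("config",
            "source and target prototype seed ranges overlap ([%d,%d] vs [%d,%d])",
            s_rng[1], s_rng[2], t_rng[1], t_rng[2])
  list(source = generate_dataset(source_cfg),
       target = generate_dataset(target_cfg))
}

#' Write a dataset to disk in folder-per-class layout
#'
#' Writes `<root>/<class_name>/<idx>.png` plus `manifest.tsv` (path, label)
#' and `meta.yaml` echoing the generator configuration. The same layout and
#' manifest serve datasets of real photographs.
#'
#' @param ds a `labeled_dataset`.
#' @param root output directory (created if missing).
#' @return `root`, invisibly.
#' @export
write_dataset <- function(ds, root) {
  cn_assert(inherits(ds, "labeled_dataset"), "input", "ds must be a labeled_dataset")
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  counter <- integer(length(ds$class_names))
  rows <- vector("list", length(ds$images))
  for (i in seq_along(ds$images)) {
    k <- ds$labels[i] + 1L
    counter[k] <- counter[k] + 1L
    rel <- file.path(ds$class_names[k], sprintf("%04d.png", counter[k]))
    dir.create(file.path(root, ds$class_names[k]), showWarnings = FALSE)
    png::writePNG(ds$images[[i]], file.path(root, rel))
    rows[[i]] <- data.frame(path = rel, label = ds$labels[i])
  }
  manifest <- do.call(rbind, rows)
  write.table(manifest, file.path(root, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(ds$config))
    yaml::write_yaml(unclass(ds$config), file.path(root, "meta.yaml"))
  writeLines(ds$class_names, file.path(root, "classes.txt"))
  invisible(root)
}

#' Read a folder-per-class dataset from disk
#'
#' @param root directory containing `manifest.tsv` as written by
#'   [write_dataset()] (or assembled for real images).
#' @return a `labeled_dataset`.
#' @export
read_dataset <- function(root) {
  mf <- file.path(root, "manifest.tsv")
  cn_assert(file.exists(mf), "input", "no manifest.tsv under %s", root)
  manifest <- read.delim(mf, stringsAsFactors = FALSE)
  images <- lapply(manifest$path, function(p) {
    img <- png::readPNG(file.path(root, p))
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
    img
  })
  cls_file <- file.path(root, "classes.txt")
  class_names <- if (file.exists(cls_file)) readLines(cls_file)
  else sort(unique(dirname(manifest$path)))
  labels <- as.integer(manifest$label)
  cn_assert(all(labels >= 0 & labels < length(class_names)), "input",
            "labels outside declared class range")
  structure(list(images = images, labels = labels,
                 class_names = class_names, config = NULL),
            class = "labeled_dataset")
}

# Stratified subset helper used by splits and low-data regimes.
subset_dataset <- function(ds, idx) {
  structure(list(images = ds$images[idx], labels = ds$labels[idx],
                 class_names = ds$class_names, config = ds$config),
            class = "labeled_dataset")
}
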