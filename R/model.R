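#' Specification of the anisotropic encoder-decoder segmentation network
#'
#' An adapted 3D U-Net for strongly anisotropic (thick-slice) volumes.
#' Each resolution level applies two 3x3x3 convolutions, each followed by
#' affine instance normalization and ReLU; the second convolution of every
#' non-bottom level doubles the channel count, so with 16 first-layer
#' filters the bottom-most level carries 128.  Pooling is anisotropic
#' max-pooling: the slice axis is pooled only at the deepest transition,
#' where the accumulated in-plane downsampling has caught up with the slice
#' spacing.  The decoder uses parameter-free (anisotropic
#' nearest-neighbour) upsampling, concatenates the encoder skip, and
#' applies two convolution blocks; a final 1x1x1 convolution with softmax
#' produces the per-class probabilities.
#'
#' With the default full-size specification the network has exactly
#' 3,197,028 trainable parameters.
#'
#' @param in_channels number of input channels (1 for grayscale volumes).
#' @param n_classes number of output classes (4: background + 3 structures).
#' @param base_filters filters in the first convolution (16 full size,
#'   4 for the reduced desk-scale network).
#' @param bottom_filters filters in the bottom-most level; must equal
#'   `base_filters * 2^(levels - 1)` for an integer number of levels.
#' @param pool_schedule optional 3 x (levels - 1) integer matrix of pooling
#'   factors (rows x, y, z); default pools 2x2 in-plane at every
#'   transition and the slice axis only at the deepest one.
#' @return an object of class `segda_model_spec`.
#' @export
model_spec <- function(in_channels = 1L, n_classes = 4L,
                       base_filters = 16L, bottom_filters = 128L,
                       pool_schedule = NULL) {
  levels <- log2(bottom_filters / base_filters) + 1
  if (abs(levels - round(levels)) > 1e-9 || levels < 2) {
    abort("`bottom_filters` must be `base_filters * 2^(levels-1)` with levels >= 2.",
          class = "segda_usage_error")
  }
  levels <- as.integer(round(levels))
  if (is.null(pool_schedule)) {
    pool_schedule <- rbind(x = rep(2L, levels - 1),
                           y = rep(2L, levels - 1),
                           z = c(rep(1L, levels - 2), 2L))
  }
  pool_schedule <- matrix(as.integer(pool_schedule), nrow = 3,
                          dimnames = list(c("x", "y", "z"), NULL))
  if (ncol(pool_schedule) != levels - 1 || any(pool_schedule < 1)) {
    abort("`pool_schedule` must be a 3 x (levels-1) matrix of factors >= 1.",
          class = "segda_usage_error")
  }
  structure(
    list(in_channels = as.integer(in_channels),
         n_classes = as.integer(n_classes),
         base_filters = as.integer(base_filters),
         bottom_filters = as.integer(bottom_filters),
         levels = levels,
         pool_schedule = pool_schedule),
    class = "segda_model_spec"
  )
}

# Layer table: one row per parameterized layer with channel counts and
# parameter group assignment.
spec_layers <- function(spec) {
  L <- spec$levels
  f <- spec$base_filters * 2^(0:(L - 1))
  rows <- list()
  addc <- function(name, cin, cout, k, group, norm = TRUE) {
    rows[[length(rows) + 1]] <<- tibble(
      name = name, type = "conv", cin = cin, cout = cout, k = k,
      group = group, norm = norm)
  }
  cin <- spec$in_channels
  for (i in seq_len(L)) {
    grp <- if (i < L) "encoder" else "bottleneck"
    c1 <- f[i]
    c2 <- if (i < L) 2L * f[i] else f[i]
    addc(sprintf("enc%d_conv1", i), cin, c1, 3L, grp)
    addc(sprintf("enc%d_conv2", i), c1, c2, 3L, grp)
    cin <- c2
  }
  dch <- cin
  for (i in rev(seq_len(L - 1))) {
    skip <- 2L * f[i]
    addc(sprintf("dec%d_conv1", i), dch + skip, skip, 3L, "decoder")
    addc(sprintf("dec%d_conv2", i), skip, skip, 3L, "decoder")
    dch <- skip
  }
  addc("out_conv", dch, spec$n_classes, 1L, "decoder", norm = FALSE)
  dplyr::bind_rows(rows)
}

#' Build a segmentation network with randomly initialized weights
#'
#' Convolution weights use He-normal initialization
#' (`sd = sqrt(2 / fan_in)`), biases start at zero, normalization scales at
#' one and shifts at zero.  The same seed reproduces the same initial
#' weights exactly.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed for the weight initialization.
#' @return an object of class `segda_model`: `list(spec, params, seed)`
#'   where `params` is a flat named list of weight matrices / vectors.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "segda_model_spec"))
  set.seed(seed)
  layers <- spec_layers(spec)
  params <- list()
  for (i in seq_len(nrow(layers))) {
    ly <- layers[i, ]
    K <- ly$k^3
    fan_in <- ly$cin * K
    params[[paste0(ly$name, "_w")]] <-
      matrix(rnorm(ly$cout * fan_in, sd = sqrt(2 / fan_in)), nrow = ly$cout)
    params[[paste0(ly$name, "_b")]] <- numeric(ly$cout)
    if (ly$norm) {
      params[[paste0(ly$name, "_ng")]] <- rep(1, ly$cout)
      params[[paste0(ly$name, "_nb")]] <- numeric(ly$cout)
    }
  }
  structure(list(spec = spec, params = params, seed = as.integer(seed),
                 layers = layers),
            class = "segda_model")
}

#' @export
print.segda_model <- function(x, ...) {
  cat(sprintf("<segda_model> %d levels, %d -> %d filters, %d classes, %s parameters\n",
              x$spec$levels, x$spec$base_filters, x$spec$bottom_filters,
              x$spec$n_classes,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable scalar parameters of a model
#'
#' @param model a [build_model()] result.
#' @return integer total over every weight, bias and normalization
#'   scale/shift.  The full-size default specification yields 3,197,028.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "segda_model"))
  sum(vapply(model$params, length, 0L))
}

#' Partition of the trainable parameters into encoder / bottleneck / decoder
#'
#' The bottom-most resolution level forms the bottleneck group; the final
#' 1x1x1 classification layer belongs to the decoder group (so it is frozen
#' together with the decoder during stage-I transfer learning).  The groups
#' are pairwise disjoint and their union is the full parameter set.
#'
#' @param model a [build_model()] result.
#' @return an object of class `segda_parameter_groups`: a list with
#'   character vectors `encoder`, `bottleneck`, `decoder` of parameter
#'   names.
#' @export
parameter_groups <- function(model) {
  stopifnot(inherits(model, "segda_model"))
  layers <- model$layers
  out <- lapply(c(encoder = "encoder", bottleneck = "bottleneck",
                  decoder = "decoder"), function(g) {
    nm <- layers$name[layers$group == g]
    intersect(names(model$params),
              unlist(lapply(nm, paste0, c("_w", "_b", "_ng", "_nb"))))
  })
  structure(out, class = "segda_parameter_groups")
}

#' @export
print.segda_parameter_groups <- function(x, ...) {
  for (g in names(x)) cat(sprintf("%-10s %d tensors\n", g, length(x[[g]])))
  invisible(x)
}

#' Parameter counts per group
#'
#' @param model a `segda_model`.
#' @return named integer vector over encoder, bottleneck, decoder.
#' @export
group_parameter_counts <- function(model) {
  groups <- parameter_groups(model)
  vapply(groups, function(nms) {
    sum(vapply(model$params[nms], length, 0L))
  }, 0L)
}

# Check that the input grid is compatible with the pooling schedule.
check_input_dims <- function(spec, dims) {
  total <- apply(spec$pool_schedule, 1, prod)
  if (any(dims %% total != 0)) {
    abort(sprintf(
      paste0("input grid %s is not divisible by the cumulative pooling ",
             "factors (%s); resample or crop the volume first."),
      paste(dims, collapse = "x"), paste(total, collapse = "x")),
      class = "segda_shape_error")
  }
  invisible(TRUE)
}

#' Predict class probabilities for a volume
#'
#' Runs the network forward in inference mode; the output is deterministic
#' for fixed weights.
#'
#' @param model a `segda_model`.
#' @param vol a [volume()] pre-processed to a grid compatible with the
#'   pooling schedule.
#' @return a [prob_map()] whose per-voxel class probabilities sum to 1.
#' @export
predict_volume <- function(model, vol) {
  stopifnot(inherits(model, "segda_model"), is_volume(vol))
  dims <- dim(vol$data)
  check_input_dims(model$spec, dims)
  x <- matrix(as.numeric(vol$data), nrow = model$spec$in_channels)
  fw <- nn_forward(model, x, dims, keep_cache = FALSE)
  prob_map(fw$probs, dims, vol$spacing, vol$origin)
}

#' @export
predict.segda_model <- function(object, newdata, ...) {
  predict_volume(object, newdata)
}

#' Save / load a model as a self-describing checkpoint
#'
#' The checkpoint is a JSON header (specification, seed) plus the flat
#' parameter vector in a binary sidecar-free single file; it can be
#' restored with [load_model()].
#'
#' @param model a `segda_model`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  spec <- model$spec
  header <- jsonlite::toJSON(list(
    spec = list(in_channels = spec$in_channels, n_classes = spec$n_classes,
                base_filters = spec$base_filters,
                bottom_filters = spec$bottom_filters,
                pool_schedule = spec$pool_schedule),
    seed = model$seed,
    tensors = lapply(model$params, function(p) {
      if (is.matrix(p)) dim(p) else length(p)
    })
  ), auto_unbox = TRUE)
  hraw <- charToRaw(as.character(header))
  writeBin(as.numeric(length(hraw)), con, size = 8, endian = "little")
  writeBin(hraw, con)
  for (p in model$params) writeBin(as.numeric(p), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hlen <- readBin(con, "numeric", n = 1, size = 8, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = hlen)))
  spec <- model_spec(in_channels = header$spec$in_channels,
                     n_classes = header$spec$n_classes,
                     base_filters = header$spec$base_filters,
                     bottom_filters = header$spec$bottom_filters,
                     pool_schedule = matrix(unlist(header$spec$pool_schedule),
                                            nrow = 3, byrow = FALSE))
  model <- build_model(spec, seed = header$seed)
  for (nm in names(header$tensors)) {
    shape <- unlist(header$tensors[[nm]])
    n <- prod(shape)
    vals <- readBin(con, "numeric", n = n, size = 8, endian = "little")
    model$params[[nm]] <- if (length(shape) == 2) {
      matrix(vals, nrow = shape[1])
    } else {
      vals
    }
  }
  model
}
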