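# Unsupervised digit-classification harness: latency-encoded images drive a
# dense plastic projection onto an output layer with adaptive thresholds and
# direct lateral inhibition; neurons are labeled afterwards by their class
# response and classification is a spike-count vote.

# stencil strokes for procedural 28x28 glyphs, one entry per digit class;
# each element is a list of segments (r1, c1, r2, c2) or rings (cr, cc, rr, rc)
.glyph_strokes <- list(
  "0" = list(ring = list(c(14, 11, 8, 4.5))),
  "1" = list(seg = list(c(5, 20, 23, 20), c(8, 16, 5, 20))),
  "2" = list(seg = list(c(7, 9, 7, 19), c(7, 19, 13, 19), c(13, 19, 21, 9), c(21, 9, 21, 19))),
  "3" = list(seg = list(c(7, 9, 7, 19), c(7, 19, 14, 19), c(14, 13, 14, 19), c(14, 19, 21, 19), c(21, 9, 21, 19))),
  "4" = list(seg = list(c(6, 16, 15, 7), c(15, 7, 15, 20), c(6, 16, 22, 16))),
  "5" = list(seg = list(c(6, 8, 6, 19), c(6, 8, 13, 8), c(13, 8, 13, 18), c(13, 18, 21, 18), c(21, 8, 21, 18))),
  "6" = list(ring = list(c(17, 13, 5, 5)), seg = list(c(6, 17, 13, 10))),
  "7" = list(seg = list(c(6, 8, 6, 20), c(6, 20, 22, 11))),
  "8" = list(ring = list(c(10, 14, 4, 4), c(19, 14, 5, 5))),
  "9" = list(ring = list(c(11, 14, 5, 5)), seg = list(c(11, 19, 22, 17)))
)

# per-digit stroke thickness, chosen so all glyphs carry a comparable pixel
# mass (~100-140 lit pixels) and hence comparable synaptic drive
.glyph_thickness <- c("0" = 1.2, "1" = 2.0, "2" = 1.4, "3" = 1.2, "4" = 1.4,
                      "5" = 1.1, "6" = 1.5, "7" = 1.7, "8" = 1.1, "9" = 1.5)

.draw_glyph <- function(digit, size = 28L,
                        thickness = .glyph_thickness[[as.character(digit)]]) {
  img <- matrix(0, size, size)
  strokes <- .glyph_strokes[[as.character(digit)]]
  rows <- matrix(rep(seq_len(size), size), size, size)
  cols <- t(rows)
  for (ring in strokes$ring %||% list()) {
    d <- sqrt(((rows - ring[1]) / ring[3])^2 + ((cols - ring[2]) / ring[4])^2)
    img[abs(d - 1) * min(ring[3:4]) <= thickness] <- 1
  }
  for (seg in strokes$seg %||% list()) {
    len <- max(abs(seg[3] - seg[1]), abs(seg[4] - seg[2]), 1)
    ts <- seq(0, 1, length.out = 2L * len + 1L)
    rr <- seg[1] + ts * (seg[3] - seg[1])
    cc <- seg[2] + ts * (seg[4] - seg[2])
    for (j in seq_along(ts)) {
      d <- sqrt((rows - rr[j])^2 + (cols - cc[j])^2)
      img[d <= thickness] <- 1
    }
  }
  img
}

#' Generate synthetic labeled digit images
#'
#' Procedural 28 x 28 grayscale glyphs with a distinct stroke pattern per
#' digit class — a desk-scale, download-free stand-in for scanned-digit
#' data (synthetic by construction, not derived from any external image
#' set). Within-class variability comes from a random integer translation
#' (up to `max_shift` pixels per axis), per-image stroke intensity drawn
#' uniformly from `[0.7, 1] * 255`, and sparse background clutter: each
#' background pixel independently receives a uniform value in `[20, 120]`
#' with probability `noise`. Like scanned digits, images are mostly zero.
#'
#' @param n_per_class Images per class.
#' @param classes Integer digit classes (subset of 0..9).
#' @param noise Background clutter probability per pixel (0 disables).
#' @param max_shift Maximum absolute translation per axis, pixels.
#' @param seed Optional RNG seed; fixed seed gives identical images.
#' @return A list with `images` (array `28 x 28 x n`) and `labels`
#'   (integer vector), classes interleaved.
#' @export
synth_digits <- function(n_per_class, classes = c(0L, 1L), noise = 0.02,
                         max_shift = 1L, seed = NULL) {
  classes <- as.integer(classes)
  stopifnot(all(classes %in% 0:9), n_per_class >= 1)
  base <- lapply(classes, .draw_glyph)
  n <- n_per_class * length(classes)
  labels <- rep(classes, n_per_class)
  with_seed(seed, {
    imgs <- array(0, dim = c(28L, 28L, n))
    for (s in seq_len(n)) {
      g <- base[[match(labels[s], classes)]]
      dr <- sample(-max_shift:max_shift, 1L)
      dc <- sample(-max_shift:max_shift, 1L)
      shifted <- matrix(0, 28L, 28L)
      src_r <- pmax(1L, 1L - dr):pmin(28L, 28L - dr)
      src_c <- pmax(1L, 1L - dc):pmin(28L, 28L - dc)
      shifted[src_r + dr, src_c + dc] <- g[src_r, src_c]
      img <- shifted * 255 * stats::runif(1, 0.7, 1)
      if (noise > 0) {
        bg <- which(shifted == 0 & stats::runif(784) < noise)
        img[bg] <- stats::runif(length(bg), 20, 120)
      }
      imgs[, , s] <- img
    }
    list(images = imgs, labels = labels)
  })
}

#' Training-harness configuration
#'
#' Defaults follow the unsupervised-training parameterization of the
#' 784-input digit network: `tau_v = 50`, `tau_g = 5` ms, baseline
#' threshold 75 with a 2.5 increment per fire and negligible decay
#' (`tau_theta = 1e7` ms), initial weights uniform in (0.45, 0.55), 100 ms
#' latency-encoded samples separated by a 150 ms rest during which state
#' decays naturally. Because every image carries a single stroke
#' intensity, its latency-encoded spikes arrive as a near-synchronous
#' volley; the conductance gain (`C = 1`) is chosen so one such volley
#' through initial weights drives well past the baseline threshold for
#' every glyph class. Lateral inhibition clears the sibling conductance
#' (strict winner-take-all per volley), so one neuron specializes per
#' presentation. STDP amplitudes default to 0.08 (LTP) and 0.02 (LTD):
#' large enough that a neuron winning a handful of times in a single
#' desk-scale epoch forms a usable receptive field, yet small enough that
#' the per-win threshold increment outweighs any potentiation a winner
#' picks up on pixels shared with other classes — so winners specialize
#' instead of monopolizing every class.
#'
#' @param n_output Output-layer size.
#' @param sample_duration Encoding window per sample, ms.
#' @param rest_interval Quiet interval between samples, ms.
#' @param encoder An [encoder_config()].
#' @param stdp An [stdp_params()].
#' @param params A [neuron_params()] for the output layer.
#' @param inhibition Lateral-inhibition mode for the output layer.
#' @param w_inh Suppression magnitude (subtract mode); defaults to the
#'   threshold baseline, i.e. near-reset suppression.
#' @param inhibit_clear_g Clear the sibling conductance on suppression (see
#'   [population()]); on by default here so each input volley elects a
#'   single winner.
#' @param w_init Range of the uniform initial weight draw.
#' @param inter_sample_reset `"decay"` lets state relax through the rest
#'   interval; `"hard"` zeroes `v` and `g_E` between samples.
#' @param epochs Passes over the training set.
#' @param seed RNG seed for the weight draw.
#' @return An object of class `harness_config`.
#' @export
harness_config <- function(n_output = 400, sample_duration = 100,
                           rest_interval = 150,
                           encoder = encoder_config("time", sample_duration),
                           stdp = stdp_params(sigma_plus = 0.08, sigma_minus = 0.02,
                                              tau_plus = 20, tau_minus = 20,
                                              w_min = 0, w_max = 1),
                           params = neuron_params(tau_v = 50, tau_g = 5, C = 1,
                                                  v_reset = 0, theta0 = 75,
                                                  theta_inc = 2.5, tau_theta = 1e7),
                           inhibition = "subtract", w_inh = params$theta0,
                           inhibit_clear_g = TRUE,
                           w_init = c(0.45, 0.55),
                           inter_sample_reset = c("decay", "hard"),
                           epochs = 1L, seed = NULL) {
  structure(list(n_input = 784L, n_output = as.integer(n_output),
                 sample_duration = as.numeric(sample_duration),
                 rest_interval = as.numeric(rest_interval),
                 encoder = encoder, stdp = stdp, params = params,
                 inhibition = inhibition, w_inh = as.numeric(w_inh),
                 inhibit_clear_g = isTRUE(inhibit_clear_g),
                 w_init = as.numeric(w_init),
                 inter_sample_reset = match.arg(inter_sample_reset),
                 epochs = as.integer(epochs), seed = seed),
            class = "harness_config")
}

.harness_network <- function(config, weights, plastic) {
  snn_network(
    n_input = config$n_input,
    populations = list(population("out", config$n_output, config$params,
                                  inhibition = config$inhibition,
                                  w_inh = config$w_inh,
                                  inhibit_clear_g = config$inhibit_clear_g)),
    projections = list(projection("input", "out", weights,
                                  plastic = plastic,
                                  stdp = if (plastic) config$stdp else NULL)))
}

.encode_sample <- function(image, config, offset) {
  r <- if (config$encoder$mode == "time") time_encode(image, config$encoder)
       else frequency_encode(image, config$encoder)
  spike_raster(r$neuron, r$time + offset, n_neurons = config$n_input)
}

#' Train the digit network by unsupervised STDP
#'
#' Presents each image in turn: the image is latency-encoded, the event
#' engine runs with STDP active for the sample window, then the network
#' rests with no input while state decays. Lateral inhibition plus the
#' adaptive threshold implement soft winner-take-all, so different neurons
#' specialize on different input patterns. Deterministic under a fixed
#' config seed.
#'
#' @param images Array `28 x 28 x n` of pixel values in `[0, 255]`.
#' @param config A [harness_config()].
#' @return An object of class `digit_model`: trained `weights`
#'   (`784 x n_output`), adapted `thresholds`, `spikes_per_sample`, and the
#'   `config`.
#' @export
train_unsupervised <- function(images, config = harness_config()) {
  n <- dim(images)[3]
  W0 <- with_seed(config$seed,
    matrix(stats::runif(config$n_input * config$n_output,
                        config$w_init[1], config$w_init[2]),
           config$n_input, config$n_output))
  net <- .harness_network(config, W0, plastic = TRUE)
  eng <- event_engine(net, engine_config())
  period <- config$sample_duration + config$rest_interval
  spikes <- integer(0)
  for (ep in seq_len(config$epochs)) {
    for (s in seq_len(n)) {
      t0 <- eng$time
      inp <- .encode_sample(images[, , s], config, t0)
      out <- engine_run(eng, inp, t0 + period)
      spikes <- c(spikes, nrow(out))
      if (config$inter_sample_reset == "hard") {
        pop <- eng$pops[[1]]
        pop$v[] <- config$params$v_reset
        pop$gE[] <- 0
      }
    }
  }
  structure(list(weights = engine_weights(eng, 1L),
                 thresholds = eng$pops[[1]]$vth,
                 spikes_per_sample = spikes,
                 config = config),
            class = "digit_model")
}

#' @export
print.digit_model <- function(x, ...) {
  cat(sprintf("digit model: 784 x %d weights, %d samples seen, mean %.2f output spikes/sample\n",
              x$config$n_output, length(x$spikes_per_sample), mean(x$spikes_per_sample)))
  invisible(x)
}

# run one image through the frozen trained network; returns per-neuron counts
.respond <- function(model, image) {
  net <- .harness_network(model$config, model$weights, plastic = FALSE)
  eng <- event_engine(net, engine_config())
  eng$pops[[1]]$vth <- model$thresholds
  inp <- .encode_sample(image, model$config, 0)
  out <- engine_run(eng, inp, model$config$sample_duration + model$config$rest_interval)
  tabulate(out$neuron, nbins = model$config$n_output)
}

#' Label output neurons by their class response
#'
#' Runs every labeled image through the frozen network (fresh state per
#' image, so the assignment is invariant to presentation order), sums
#' output spike counts per (neuron, class), and assigns each neuron the
#' class with the largest response, ties going to the lowest class index.
#' Neurons with zero spikes across all classes are unresponsive (`NA`) and
#' are excluded from voting.
#'
#' @param model A [train_unsupervised()] result.
#' @param images Array `28 x 28 x n` of labeling images.
#' @param labels Integer class labels, length `n`.
#' @return A list of class `label_assignment` with `neuron_to_class`
#'   (integer, `NA` = unresponsive) and `response_matrix`
#'   (`n_output x n_classes`).
#' @export
assign_labels <- function(model, images, labels) {
  classes <- sort(unique(as.integer(labels)))
  resp <- matrix(0, model$config$n_output, length(classes),
                 dimnames = list(NULL, as.character(classes)))
  for (s in seq_len(dim(images)[3])) {
    cl <- match(as.integer(labels[s]), classes)
    resp[, cl] <- resp[, cl] + .respond(model, images[, , s])
  }
  cls <- classes[apply(resp, 1L, which.max)] # which.max ties -> first = lowest class
  cls[rowSums(resp) == 0] <- NA_integer_
  structure(list(neuron_to_class = cls, response_matrix = resp, classes = classes),
            class = "label_assignment")
}

#' @export
print.label_assignment <- function(x, ...) {
  cat("neuron labeling:\n")
  print(table(factor(x$neuron_to_class, levels = x$classes), useNA = "ifany"))
  invisible(x)
}

#' Classify images with a labeled network
#'
#' Each image is run through the frozen network; the score of a class is
#' the mean spike count of the neurons assigned to it, and the prediction
#' is the argmax (ties to the lowest class index). An image eliciting no
#' spikes from any labeled neuron yields `NA` (abstention).
#'
#' @param model A [train_unsupervised()] result.
#' @param assignment An [assign_labels()] result.
#' @param images Array `28 x 28 x n`.
#' @return Integer vector of predicted classes (`NA` = abstention).
#' @export
classify <- function(model, assignment, images) {
  cls <- assignment$classes
  members <- lapply(cls, function(cl) which(!is.na(assignment$neuron_to_class) &
                                              assignment$neuron_to_class == cl))
  n <- dim(images)[3]
  pred <- rep(NA_integer_, n)
  for (s in seq_len(n)) {
    counts <- .respond(model, images[, , s])
    score <- vapply(members, function(m) if (length(m)) mean(counts[m]) else 0, numeric(1))
    if (sum(score) > 0) pred[s] <- cls[which.max(score)]
  }
  pred
}

#' Evaluate classification accuracy
#'
#' @param model A [train_unsupervised()] result.
#' @param assignment An [assign_labels()] result.
#' @param images Array `28 x 28 x n` of held-out images.
#' @param labels True class labels.
#' @return A list with `accuracy` (abstentions count as errors),
#'   `predictions`, and a `confusion` matrix (rows = true class, columns =
#'   predicted class plus abstentions).
#' @export
evaluate_classifier <- function(model, assignment, images, labels) {
  pred <- classify(model, assignment, images)
  labels <- as.integer(labels)
  lv <- sort(unique(c(labels, assignment$classes)))
  confusion <- table(true = factor(labels, levels = lv),
                     predicted = factor(pred, levels = lv), useNA = "ifany")
  list(accuracy = mean(!is.na(pred) & pred == labels),
       predictions = pred, confusion = confusion)
}
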