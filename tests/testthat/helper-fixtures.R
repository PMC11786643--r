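# Shared fixtures, all generated in code at test time.

# the hand-checked bivariate VAR(1): A1 = [[0.5, 0], [0.4, 0.5]]
bivar_A1 <- function() matrix(c(0.5, 0.4, 0, 0.5), 2, 2)

# an mvar_model built directly from known coefficients (no fitting)
model_from_coefs <- function(A, fs = 128, sigma = NULL) {
  m <- nrow(A[[1L]])
  structure(list(order = length(A), A = A,
                 sigma = sigma %||% diag(m), fs = fs,
                 labels = sprintf("ch%02d", seq_len(m)),
                 kinds = rep("EEG", m), n_eff = 1000L, diagnostics = NULL),
            class = "mvar_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

white_window <- function(m, n, fs = 128, seed = 1) {
  set.seed(seed)
  ecimage:::as_window(matrix(rnorm(m * n), m, n), fs = fs)
}

# random stable MVAR coefficient list
random_stable_A <- function(m, P, seed, scale = 0.3) {
  set.seed(seed)
  A <- lapply(seq_len(P), function(r) matrix(rnorm(m * m, sd = scale / r), m, m))
  ecimage:::stabilize_coefficients(A, target = 0.9, trigger = 0.95)
}

# 35-channel recording with the canonical montage labels
canonical_recording <- function(n = 1280, fs = 128, seed = 1, emotion = NULL) {
  set.seed(seed)
  recording(matrix(rnorm(35 * n), 35, n), fs,
            labels = canonical_montage(), emotion = emotion)
}

# solid-colour image fixture: 4 classes of distinct brightness
solid_image_set <- function(n_per_class = 40, size = 16, seed = 1) {
  set.seed(seed)
  mk <- function(val) array(rep(val, size * size), c(size, size, 3)) +
    array(runif(size * size * 3, 0, 0.05), c(size, size, 3))
  vals <- c(0.1, 0.35, 0.6, 0.9)
  imgs <- unlist(lapply(vals, function(v)
    lapply(seq_len(n_per_class), function(i) mk(v))), recursive = FALSE)
  list(images = imgs,
       labels = factor(rep(emotion_classes(), each = n_per_class),
                       levels = emotion_classes()))
}

# ---- independent byte-level EDF/BDF builders (format oracle) -----------

pad_field <- function(s, width) {
  s <- as.character(s)
  if (nchar(s) > width) stop("field too wide")
  charToRaw(formatC(s, width = -width))   # left-justified, space padded
}

# one-record EDF with explicit digital samples per signal
build_edf_bytes <- function(labels, fs, digital, phys_min, phys_max,
                            dig_min = -32768, dig_max = 32767, bdf = FALSE) {
  ns <- length(labels)
  spr <- length(digital[[1L]])
  hdr <- c(
    if (bdf) c(as.raw(0xFF), charToRaw("BIOSEMI")) else pad_field("0", 8),
    pad_field("patient", 80), pad_field("rec", 80),
    pad_field("01.01.20", 8), pad_field("00.00.00", 8),
    pad_field(256 + 256 * ns, 8), pad_field("", 44),
    pad_field(1, 8), pad_field(format(spr / fs), 8), pad_field(ns, 4))
  sig <- c(
    unlist(lapply(labels, pad_field, width = 16)),
    unlist(lapply(rep("", ns), pad_field, width = 80)),
    unlist(lapply(rep("uV", ns), pad_field, width = 8)),
    unlist(lapply(rep(phys_min, ns), pad_field, width = 8)),
    unlist(lapply(rep(phys_max, ns), pad_field, width = 8)),
    unlist(lapply(rep(dig_min, ns), pad_field, width = 8)),
    unlist(lapply(rep(dig_max, ns), pad_field, width = 8)),
    unlist(lapply(rep("", ns), pad_field, width = 80)),
    unlist(lapply(rep(spr, ns), pad_field, width = 8)),
    unlist(lapply(rep("", ns), pad_field, width = 32)))
  data <- unlist(lapply(digital, function(d) {
    if (bdf) {
      v <- ifelse(d < 0, d + 16777216, d)
      as.raw(as.vector(rbind(v %% 256, (v %/% 256) %% 256, v %/% 65536)))
    } else {
      writeBin(as.integer(d), raw(), size = 2L, endian = "little")
    }
  }))
  c(hdr, sig, data)
}

# mock pretrained network for the transfer adapter: brightness-tuned
# radial-basis features (stand-in for high-margin penultimate activations)
mock_network <- function() {
  centres <- seq(0.05, 0.95, length.out = 16)
  list(features = function(images) {
    t(vapply(images, function(im) {
      px <- if (inherits(im, "connectivity_image")) im$pixels / 255 else im
      m <- mean(px)
      c(mean(px[, , 1]), mean(px[, , 2]), mean(px[, , 3]),
        exp(-(m - centres)^2 / 0.005))
    }, numeric(19)))
  }, final_fc = list(units = 1000L))
}

# mock prediction handle with fixed probabilities (for evaluate())
mock_handle <- function(probs) structure(list(probs = probs),
                                         class = "mock_pred")
registerS3method("predict_proba", "mock_pred",
                 function(handle, images) handle$probs,
                 envir = asNamespace("ecimage"))
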