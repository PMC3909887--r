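#' Finger joint angle table for the counting configurations
#'
#' Joint angles (degrees) of a two-handed humanoid hand model for the rest
#' position and the ten finger-counting configurations. Each hand contributes
#' 7 degrees of freedom: two joints each for thumb, index and middle finger,
#' and a single joint driving the mechanically coupled ring+pinky pair.
#' Numbers one to five are shown on the right hand; six to ten add left-hand
#' fingers while the right hand stays fully open. High values mean a closed
#' finger (nominally 90/180/220), low values an open one; the stored values
#' are the actual reachable positions, slightly off the nominal ones because
#' of self-collision and tendon limits.
#'
#' @return An object of class `finger_joint_table`: a list with
#'   * `labels` — configuration names (`rest`, `one` .. `ten`),
#'   * `values` — an 11 x 14 numeric matrix (configurations x joints),
#'   * `joint_names` — the 14 joint identifiers (right hand first).
#' @seealso [mfcc_table()], [normalize_features()], [perturb_table()]
#' @export
#' @examples
#' tab <- finger_joint_table()
#' tab$values["four", "right_ring_pinky"]
finger_joint_table <- function() {
  joint_names <- c(
    "right_thumb_j1", "right_thumb_j2",
    "right_index_j1", "right_index_j2",
    "right_middle_j1", "right_middle_j2",
    "right_ring_pinky",
    "left_thumb_j1", "left_thumb_j2",
    "left_index_j1", "left_index_j2",
    "left_middle_j1", "left_middle_j2",
    "left_ring_pinky"
  )
  labels <- c("rest", "one", "two", "three", "four", "five",
              "six", "seven", "eight", "nine", "ten")
  left_rest <- c(90, 180, 90, 180, 90, 180, 220)
  right_open <- c(11.1, 1.2, 0, 0, 0, 0, 0)
  values <- rbind(
    rest  = c(90, 180, 90, 180, 90, 180, 220, left_rest),
    one   = c(90, 180, 1.1, 2.2, 90, 180, 220, left_rest),
    two   = c(90, 180, 0, 0, 1.1, 2.2, 220, left_rest),
    three = c(10.9, 2.1, 0, 0, 0, 0, 220, left_rest),
    four  = c(88.9, 88.8, 0, 0, 0, 0, 3.0, left_rest),
    five  = c(right_open, left_rest),
    six   = c(right_open, 90, 180, 1.0, 2.1, 90, 180, 220),
    seven = c(right_open, 90, 180, 0, 0, 1.0, 2.1, 220),
    eight = c(right_open, 11.0, 2.2, 0, 0, 0, 0, 220),
    nine  = c(right_open, 89.0, 88.9, 0, 0, 0, 0, 2.7),
    ten   = c(right_open, 11.0, 1.2, 0, 0, 0, 0, 0)
  )
  colnames(values) <- joint_names
  structure(
    list(labels = labels, values = values, joint_names = joint_names),
    class = c("finger_joint_table", "countnet_table")
  )
}

#' Mel-frequency cepstral coefficients for the spoken number words
#'
#' Thirteen MFCCs per number word (one to ten), extracted from recordings of
#' a child's voice sampled at 22 kHz. The first coefficient is the
#' energy-like term and dominates every row (all below -29); the remaining
#' twelve are small spectral-shape terms. These coefficients are the
#' system's auditory input; no audio processing happens in this package.
#'
#' @return An object of class `mfcc_table`: a list with
#'   * `labels` — word names (`one` .. `ten`),
#'   * `values` — a 10 x 13 numeric matrix (words x coefficients `c1` .. `c13`).
#' @export
#' @examples
#' mfcc_table()$values["five", "c3"]
mfcc_table <- function() {
  # words x 13 coefficients
  values <- rbind(
    one   = c(-35.5929, -1.0919, 0.4216, -0.1042, 0.3303, -0.1156, 0.0052,
              -0.1069, -0.1343, 0.1164, -0.5587, -0.1981, 0.223),
    two   = c(-32.9669, -1.3581, 1.1045, 0.2708, 0.0268, 0.3903, 0.1658,
              0.0182, -0.1744, -0.1774, 0.3471, -0.0564, -0.0566),
    three = c(-32.4777, -1.5224, 0.6798, -0.0635, 0.2202, -0.0071, -0.0939,
              0.0204, 0.0419, 0.0226, -0.0303, 0.1463, -0.0506),
    four  = c(-31.2712, -1.8495, 0.0099, -0.3179, 0.0331, -0.3468, 0.3523,
              0.3312, 0.1559, -0.0661, -0.0531, 0.0979, 0.033),
    five  = c(-29.7136, -1.4493, -0.6858, -0.4566, 0.507, 0.3923, -0.3028,
              -0.1998, -0.1472, -0.1542, 0.3098, 0.2068, -0.0655),
    six   = c(-35.4331, -1.2686, 0.7221, 0.184, -0.08, 0.0328, 0.1184,
              -0.4751, 0.0975, 0.5202, -0.1306, -0.0164, 0.0037),
    seven = c(-35.442, -1.0689, 0.6448, 0.1756, -0.2727, 0.0277, 0.7074,
              0.036, 0.2879, 0.1546, 0.155, -0.2105, -0.1311),
    eight = c(-32.0295, -1.9539, 0.6668, 0.2295, -0.0303, -0.2201, 0.0011,
              -0.0101, 0.1467, 0.1802, 0.0578, 0.2783, -0.0695),
    nine  = c(-31.2157, -1.1709, 0.1402, 0.7539, -0.4317, -0.189, 0.9789,
              0.3488, -0.2435, 0.4552, -0.1662, -0.2708, -0.176),
    ten   = c(-31.9479, -2.0959, 0.5683, -0.2115, -0.2456, 0.1962, 0.2468,
              0.4278, 0.5773, -0.1427, -0.0612, -0.0456, 0.0915)
  )
  colnames(values) <- paste0("c", 1:13)
  structure(
    list(labels = rownames(values), values = values),
    class = c("mfcc_table", "countnet_table")
  )
}

#' @export
print.countnet_table <- function(x, ...) {
  cat(sprintf("<%s> %d x %d\n", class(x)[1], nrow(x$values), ncol(x$values)))
  print(utils::head(round(x$values, 4)))
  invisible(x)
}

#' Scale a matrix to the [-1, 1] range
#'
#' Divides entries by the maximum absolute value, either per feature (each
#' column scaled by its own maximum, the default — sensible when features
#' live on very different scales, as the first MFCC does) or globally (one
#' divisor for the whole matrix). Zero columns pass through unchanged in
#' per-feature mode. The divisors are retained so the transform can be
#' inverted with [denormalize()] or re-applied to new vectors.
#'
#' @param x numeric matrix (or a fixture table, whose `$values` are used).
#' @param mode `"per_feature"` or `"global"`.
#' @return An object of class `normalized_matrix`: list with `values`
#'   (all entries in `[-1, 1]`), `scale_factors` (per-column divisors;
#'   recycled scalar in global mode) and `mode`.
#' @export
#' @examples
#' nm <- normalize_features(mfcc_table())
#' range(nm$values)
normalize_features <- function(x, mode = c("per_feature", "global")) {
  mode <- match.arg(mode)
  if (inherits(x, "countnet_table")) x <- x$values
  x <- as.matrix(x)
  if (length(x) == 0L) stop("cannot normalize an empty matrix")
  if (mode == "per_feature") {
    s <- apply(abs(x), 2L, max)
    s[s == 0] <- 1  # zero columns pass through
  } else {
    smax <- max(abs(x))
    if (smax == 0) stop("degenerate scale: all-zero matrix in global mode")
    s <- rep(smax, ncol(x))
  }
  values <- sweep(x, 2L, s, "/")
  structure(list(values = values, scale_factors = s, mode = mode),
            class = "normalized_matrix")
}

#' Invert a [normalize_features()] transform
#'
#' @param nm a `normalized_matrix`.
#' @return The original numeric matrix.
#' @export
denormalize <- function(nm) {
  stopifnot(inherits(nm, "normalized_matrix"))
  sweep(nm$values, 2L, nm$scale_factors, "*")
}

#' Apply stored scale factors to new data
#'
#' Scales a vector or matrix by the per-feature divisors recorded in a
#' `normalized_matrix`, so that novel observations (e.g. a heard word's
#' MFCC vector, or a transferred hidden state) land in the same normalized
#' space as the training data.
#'
#' @param nm a `normalized_matrix`.
#' @param x numeric vector (length = n features) or matrix (columns = features).
#' @return Scaled object of the same shape.
#' @export
apply_scale <- function(nm, x) {
  stopifnot(inherits(nm, "normalized_matrix"))
  if (is.matrix(x)) {
    stopifnot(ncol(x) == length(nm$scale_factors))
    sweep(x, 2L, nm$scale_factors, "/")
  } else {
    stopifnot(length(x) == length(nm$scale_factors))
    x / nm$scale_factors
  }
}

#' Add seeded Gaussian noise to a fixture table
#'
#' Robustness helper: returns a copy of the table with independent
#' zero-mean Gaussian noise (standard deviation `sigma`, in the table's own
#' units) added to every entry. `sigma = 0` returns an identical copy.
#'
#' @param table a `finger_joint_table` or `mfcc_table`.
#' @param sigma noise standard deviation, `>= 0`.
#' @param seed integer seed; the same seed always yields the same noise.
#' @return A table of the same class with perturbed `values`.
#' @export
perturb_table <- function(table, sigma, seed) {
  stopifnot(inherits(table, "countnet_table"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("sigma must be a single non-negative number")
  if (sigma == 0) return(table)
  out <- table
  noise <- with_seed(seed, stats::rnorm(length(table$values), 0, sigma))
  out$values <- table$values + matrix(noise, nrow(table$values))
  out
}

#' Write a fixture table to CSV
#'
#' Plain UTF-8 CSV with a header row of joint/coefficient names, one row per
#' configuration/word, '.' decimal separator, full precision (entries survive
#' a round trip bit-exactly).
#'
#' @param table a `finger_joint_table` or `mfcc_table`.
#' @param path output file path.
#' @export
write_table_csv <- function(table, path) {
  stopifnot(inherits(table, "countnet_table"))
  df <- data.frame(label = table$labels,
                   format(table$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = FALSE)
}

#' Read a fixture table written by [write_table_csv()]
#'
#' @param path CSV file path.
#' @param class_hint `"finger_joint_table"` or `"mfcc_table"`.
#' @return A table object of the hinted class.
#' @export
read_table_csv <- function(path, class_hint = c("finger_joint_table", "mfcc_table")) {
  class_hint <- match.arg(class_hint)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$label
  out <- list(labels = df$label, values = values)
  if (class_hint == "finger_joint_table") out$joint_names <- colnames(values)
  structure(out, class = c(class_hint, "countnet_table"))
}

# Run code under a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
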