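# Small in-code fixtures shared across test files.

rf_prob_for_test <- function(m, x)
  predict(m, data = as.data.frame(x), num.threads = 1)$predictions[, "1"]

# band-power tensor with hand-chosen values
make_bp <- function(values, centers = NULL,
                    bands = names(canonical_bands())) {
  if (is.null(centers)) centers <- seq_len(dim(values)[3])
  structure(list(values = values, band_names = bands[seq_len(dim(values)[2])],
                 window_centers_s = centers),
            class = "band_power_tensor")
}

# minimal recording without the generator's duration/fs constraints
make_rec <- function(signal, fs = 500, ...) new_recording(signal, fs, ...)

# separable per-band feature set for SRFE tests: informative_band carries
# label * shift, everything else is noise.  Rows: patients x seizures x units.
make_separable_features <- function(n_patients = 4, n_seizures = 2,
                                    n_units = 6, n_pos = 1, w = 8,
                                    shift = 10, informative_band = "gamma",
                                    seed = 7, label_fun = NULL) {
  set.seed(seed)
  bands <- names(canonical_bands())
  meta <- expand.grid(electrode = sprintf("e%02d", seq_len(n_units)),
                      seizure_id = sprintf("S%02d", seq_len(n_seizures)),
                      patient_id = sprintf("P%02d", seq_len(n_patients)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta <- meta[, c("patient_id", "seizure_id", "electrode")]
  meta$label <- as.integer(as.integer(sub("e", "", meta$electrode)) <= n_pos)
  if (!is.null(label_fun)) meta$label <- label_fun(meta)
  meta$true_soz <- meta$label
  n <- nrow(meta)
  band_x <- lapply(bands, function(b) {
    m <- matrix(rnorm(n * w), n, w)
    if (b == informative_band) m <- m + shift * meta$label
    m
  })
  names(band_x) <- bands
  structure(list(meta = meta, band_x = band_x),
            class = "electrode_features")
}
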