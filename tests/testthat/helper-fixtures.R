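# Shared fixtures, built once per test run and memoised.

.hq_cache <- new.env(parent = emptyenv())

# small, fast phantom geometry used where full default size is unnecessary
small_phantom_spec <- function(seed = 1L, ...) {
  phantom_spec(shape = c(16L, 64L, 64L), seed = seed, ...)
}

cached <- function(key, builder) {
  if (!exists(key, envir = .hq_cache)) {
    assign(key, builder(), envir = .hq_cache)
  }
  get(key, envir = .hq_cache)
}

# phantom + preprocessing for a given seed (default geometry)
prepped_phantom <- function(seed, spec = NULL) {
  key <- paste0("prep_", seed, "_", is.null(spec))
  cached(key, function() {
    if (is.null(spec)) spec <- phantom_spec(seed = seed)
    ph <- generate_hand_phantom(spec)
    bc <- correct_bias_field(ph$t1)
    hm <- extract_hand_mask(bc$corrected)
    list(ph = ph, corrected = bc$corrected, field = bc$field, hand = hm)
  })
}

# classifier trained on three default-geometry phantoms
test_classifier <- function() {
  cached("classifier", function() {
    train_phantom_classifier(seeds = c(101L, 102L, 103L))
  })
}

dice_coef <- function(a, b) {
  da <- if (is.list(a)) a$data else a
  db <- if (is.list(b)) b$data else b
  2 * sum(da == 1 & db == 1) / (sum(da == 1) + sum(db == 1))
}
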