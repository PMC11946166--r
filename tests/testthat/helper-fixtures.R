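## Shared fixtures, memoized across test files (geometry and the
## sensitivity matrix are deterministic; sessions are seeded).

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

test_montage <- function() memo("montage", default_brite_montage())
test_mesh <- function() memo("mesh", default_cortex_mesh(test_montage()))
test_scouts <- function() memo("scouts",
                               default_scouts(test_mesh(), test_montage()))
test_sens <- function() memo("sens",
                             build_sensitivity(test_montage(), test_mesh()))

## A short two-piece script (one piece > 180 s) for fast end-to-end runs.
short_script <- function(concert_index = 1L) {
  concert_script(
    data.frame(id = c("p1", "p2"),
               start = c(30, 260),
               duration = c(200, 40)),
    concert_index = concert_index
  )
}

## One short session, memoized per seed/truth tag.
short_session <- function(seed = 7, truth = ground_truth(),
                          performers = "second", tag = "default") {
  memo(sprintf("sess_%s_%d_%s", tag, seed,
               paste(performers, collapse = "+")),
       generate_session(short_script(), test_montage(), test_sens(),
                        test_scouts(), truth, seed = seed,
                        performers = performers))
}

## The full seven-concert fixture (heavy; built once).
full_fixture <- function(seed = 42) {
  memo(sprintf("fixture_%d", seed),
       default_fixture(seed = seed, montage = test_montage(),
                       mesh = test_mesh(), scouts = test_scouts(),
                       sens = test_sens()))
}

## Noise-free ground truth for deterministic chains.
quiet_truth <- function(superficial_amp = c(mayer = 0, resp = 0, cardiac = 0),
                        noise_sd = 0) {
  gt <- ground_truth()
  gt$superficial$amp <- superficial_amp
  gt$noise_sd <- noise_sd
  gt$drift_amp <- 0
  gt$motion_rate_hz <- 0
  gt
}

## Build a minimal nirs_od directly from a channel matrix.
od_from_matrix <- function(mat, montage = test_montage(), fs = 75) {
  colnames(mat) <- montage$channels$id
  structure(list(data = mat, fs = fs, channels = montage$channels,
                 montage = montage, bad = character(0)),
            class = "nirs_od")
}
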