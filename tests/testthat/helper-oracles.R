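# Independent oracles used across the suite. These deliberately re-derive
# results with naive, per-pixel / exhaustive code paths.

# Exhaustive Otsu: try all 255 inter-bin splits of a 256-bin min-max
# histogram, maximizing w0*w1*(m0-m1)^2; ties keep the lowest bin.
brute_otsu <- function(v, nbins = 256L) {
  v <- v[is.finite(v)]
  mn <- min(v)
  mx <- max(v)
  stopifnot(mx > mn)
  bin <- pmin(floor((v - mn) / (mx - mn) * nbins), nbins - 1L)
  cnt <- tabulate(bin + 1L, nbins)
  n <- sum(cnt)
  lv <- 0:(nbins - 1L)
  best <- -Inf
  best_k <- NA_integer_
  for (k in 0:(nbins - 2L)) {
    i0 <- 1:(k + 1L)
    w0 <- sum(cnt[i0])
    w1 <- n - w0
    if (w0 == 0L || w1 == 0L) next
    m0 <- sum(lv[i0] * cnt[i0]) / w0
    m1 <- sum(lv[-i0] * cnt[-i0]) / w1
    s2 <- (w0 / n) * (w1 / n) * (m0 - m1)^2
    if (s2 > best) {
      best <- s2
      best_k <- k
    }
  }
  mn + (best_k + 1L) * (mx - mn) / nbins
}

# Naive scalar evaluation of every registered layer formula at one pixel.
# px: list with scalars R, G, B (digital numbers) and Blue, Green, Red,
# RedEdge, NIR (reflectance).
naive_vi <- function(name, px) {
  R <- px$R; G <- px$G; B <- px$B
  tot <- R + G + B
  r <- R / tot; g <- G / tot; b <- B / tot
  exg <- 2 * g - r - b
  exr <- 1.4 * r - g
  cive <- 0.411 * R - 0.811 * G + 0.385 * B + 18.78745
  veg <- G / (R^0.667 * B^0.333)
  N <- px$NIR; Rd <- px$Red; Gr <- px$Green
  switch(name,
    R = R, G = G, B = B, r = r, g = g, b = b,
    NGRDI = (g - r) / (g + r),
    GLI = (2 * g - r - b) / (2 * g + r + b),
    VARI = (g - r) / (g + r - b),
    ExR = exr,
    ExG = exg,
    ExB = 1.4 * b - g,
    ExGR = exg - exr,
    CIVE = cive,
    VEG = veg,
    MExG = 1.262 * G - 0.884 * R - 0.311 * B,
    IKAW = (R - B) / (R + B),
    TGI = 0.5 * (0.19 * (R - G) - 0.12 * (R - B)),
    COM1 = exg + cive + (exg - exr) + veg,
    COM2 = 0.36 * exg + 0.47 * cive + 0.17 * veg,
    Blue = px$Blue, Green = Gr, Red = Rd, RedEdge = px$RedEdge, NIR = N,
    NDVI = (N - Rd) / (N + Rd),
    GNDVI = (N - Gr) / (N + Gr),
    RVI = N / Rd,
    DVI = N - Rd,
    RDVI = (N - Rd) / sqrt(N + Rd),
    SAVI = (1 + 0.5) * (N - Rd) / (N + Rd + 0.5),
    CI = N / Gr - 1,
    NLI = (N * N - Rd) / (N * N + Rd),
    MNLI = (1 + 0.5) * (N * N - Rd) / (N * N + Rd + 0.5),
    TVI = 60 * (N - Gr) - 100 * (Rd - Gr),
    EVI2 = 2.5 * (N - Rd) / (N + 2.4 * Rd + 1),
    MSAVI2 = (2 * N + 1 - sqrt((2 * N + 1)^2 - 8 * (N - Rd))) / 2,
    OSAVI = (N - Rd) / (N + Rd + 0.16),
    MCARI = 1.5 * (2.5 * (N - Rd) - 1.3 * (N - Gr)) /
      sqrt((2 * N + 1)^2 - (6 * N - 5 * sqrt(Rd)) - 0.5),
    stop("oracle: unknown index ", name)
  )
}

# Random scene with independent uniform channel values (no spatial
# structure) for formula-equivalence checks.
random_scene <- function(h, w, seed) {
  with_seed_test(seed, {
    vis <- array(runif(h * w * 3, 0, 255), c(h, w, 3))
    refl <- array(runif(h * w * 5, 0.001, 1), c(h, w, 5))
    multiband_scene(visible = vis, reflectance = refl)
  })
}

# Seed helper local to the test suite (mirrors the package-internal one
# without reaching into unexported code).
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# A tiny one-pixel scene with prescribed channel values.
pixel_scene <- function(R = 0, G = 0, B = 0, Blue = 0.1, Green = 0.1,
                        Red = 0.1, RedEdge = 0.1, NIR = 0.1) {
  multiband_scene(
    visible = array(c(R, G, B), c(1, 1, 3)),
    reflectance = array(c(Blue, Green, Red, RedEdge, NIR), c(1, 1, 5))
  )
}

value_at <- function(scene, name) compute_index(scene, name)$values[1, 1]
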