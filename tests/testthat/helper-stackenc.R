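# shared fixture builders (all programmatic; no data files)

# small random design list for stacking tests
random_designs <- function(Tn, spaces = c("a", "b"), p = 3, seed = 1) {
  set.seed(seed)
  out <- lapply(spaces, function(s) matrix(stats::rnorm(Tn * p), Tn))
  names(out) <- spaces
  out
}

# an atlas data frame over G grayordinates split evenly into parcels
toy_atlas <- function(G, parcels) {
  data.frame(grayordinate = seq_len(G),
             parcel = rep(parcels, each = ceiling(G / length(parcels)),
                          length.out = G),
             hemisphere = "L")
}

# frozen 55-point vector for the D'Agostino oracle comparison
dagostino_fixture <- function() {
  c(0.1, -1.2, 2.3, 0.5, -0.7, 1.1, 0.0, -0.3, 0.8, -1.5,
    2.0, 0.4, -0.9, 1.7, -0.2, 0.6, -1.1, 0.9, 0.3, -0.6,
    1.4, -0.8, 0.2, -1.3, 0.7, 1.9, -0.4, 0.1, -1.0, 0.5,
    3.2, -2.1, 0.0, 1.2, -0.5, 0.8, 2.5, -1.7, 0.4, 0.9,
    -0.1, 1.6, -2.3, 0.3, 0.7, -1.4, 2.8, 0.2, -0.9, 1.0,
    0.6, -0.3, 1.8, -1.6, 0.5)
}
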