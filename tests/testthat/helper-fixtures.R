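# fixtures are built in code; nothing is read from disk

# two touching discs with distinct labels (overlap pixels go to label 2)
touching_discs <- function(shape = c(64, 64), r = 10) {
  lab <- matrix(0L, shape[1], shape[2])
  lab[disc_mask(shape, c(32, 22), r)] <- 1L
  lab[disc_mask(shape, c(32, 22 + 2 * r), r)] <- 2L
  lab
}

# IoU of two binary masks
iou <- function(a, b) sum(a & b) / sum(a | b)

# greedy best-IoU matching of predicted labels onto truth labels
match_objects <- function(pred, truth) {
  np <- max(pred); nt <- max(truth)
  if (np == 0L || nt == 0L) return(numeric(0))
  vapply(seq_len(nt), function(i) {
    tm <- truth == i
    cand <- unique(pred[tm & pred > 0L])
    if (length(cand) == 0L) return(0)
    max(vapply(cand, function(j) iou(pred == j, tm), numeric(1)))
  }, numeric(1))
}

# small, fast cohort for end-to-end tests
tiny_config <- function(...) {
  defaults <- list(image_shape = c(160, 160), n_spores = 4L, n_frames = 8L,
                   germ_tube_max_len = 20)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# exact two-sided Mann-Whitney p by full enumeration of rank assignments
mw_exact_p <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(n, nx)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * (n - nx) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}
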