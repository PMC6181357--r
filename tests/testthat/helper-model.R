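# shared fixtures: default parameterisation and a few analytic constants
P <- nest_params()
MOC_MAX <- carrying_capacity(P$mfa, P$mfap)            # 33.333 pairs
TN_EQ <- equilibrium_total_nests(MOC_MAX, P$nbr, P$nlf) # 96.507 nests

# build a bare trajectory data.frame for metric tests
fake_traj <- function(year, on, moc, id = "fake") {
  tr <- data.frame(year = year, on = on, moc = moc)
  class(tr) <- c("nest_trajectory", "data.frame")
  tr
}

# independent integration oracle: the same clamped flow field handed to lsoda
lsoda_unmanaged <- function(on0, tn0, moc, params, times) {
  rhs <- function(t, y, parms) {
    on <- y[1]; tn <- y[2]
    if (moc > 0) {
      anr <- min(1, max(0, (moc - on) / moc))
      or <- min(1, max(0, on / moc))
      onir <- anr * or * (tn - on) * params$cr
      onar <- max(0, (on - moc) * params$cr)
    } else {
      onir <- 0; onar <- on * params$cr
    }
    list(c(onir - onar, on * params$nbr - tn / params$nlf))
  }
  deSolve::lsoda(c(on = on0, tn = tn0), times, rhs, NULL,
                 rtol = 1e-10, atol = 1e-10)
}
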