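test_that("the proportional law is linear in the error", {
  g <- pi_gains(kp = 0.1)
  expect_equal(p_step(0, g), 0)
  expect_equal(p_step(50, g), 5)
  expect_equal(p_step(-50, g), -5)
  for (kp in c(0.01, 0.1, 1, 10))
    expect_equal(p_step(3, pi_gains(kp = kp)), 3 * kp)
})

test_that("the PI law integrates and respects its anti-windup bound", {
  g <- pi_gains(kp = 0, ki = 1, anti_windup = 100)
  u <- 0
  for (i in 1:10) {
    st <- pi_step(1, 0.5, g)
    g <- st$gains
    u <- st$u
  }
  expect_equal(u, 5)  # pure integrator: e*t
  for (i in 1:1000) g <- pi_step(1, 1, g)$gains
  expect_equal(g$integral_state, 100)
  g2 <- pi_gains(kp = 0.5, ki = 0.5)
  expect_equal(pi_step(2, 0.1, g2)$u, 0.5 * 2 + 0.5 * 0.2)
  expect_error(pi_step(1, 0, g2), "dt")
})

test_that("the RBF forward pass evaluates its Gaussian units", {
  st <- rbf_state(m = 2, centers = c(0, 1), widths = 1, seed = 1)
  st$w <- c(1, 1)
  fw <- rbf_forward(0, st)
  expect_equal(fw$h, c(1, exp(-1 / 2)))
  expect_equal(fw$u_rbf, 1 + exp(-1 / 2))
  st$w <- c(0, 0)
  expect_equal(rbf_forward(0.3, st)$u_rbf, 0)
})

test_that("the five-node preset reproduces the compact parameter vectors", {
  st <- rbf_state(five_node = TRUE)
  expect_equal(st$c, c(-2, -1, 0, 1, 2))
  expect_equal(st$b, rep(5, 5))
  expect_equal(st$m, 5)
  d <- rbf_state()
  expect_equal(d$m, 11)
  expect_equal(range(d$c), c(-2, 2))
  expect_true(all(d$w >= 0 & d$w <= 1))
})

test_that("RBF gradients match central-difference differentiation", {
  set.seed(4)
  for (rep in 1:5) {
    m <- sample(2:6, 1)
    st <- rbf_state(m = m, centers = stats::runif(m, -2, 2),
                    widths = stats::runif(m, 0.5, 3),
                    eta = 0.3, alpha = 0, seed = rep)
    x <- stats::runif(1, -2, 2)
    u <- stats::runif(1, 0, 10)
    fw <- rbf_forward(x, st)
    upd <- rbf_update(u, fw$u_rbf, fw$h, x, st)
    E <- function(w, b, c) {
      s2 <- st
      s2$w <- w; s2$b <- b; s2$c <- c
      0.5 * (rbf_forward(x, s2)$u_rbf - u)^2
    }
    h <- 1e-6
    for (j in seq_len(m)) {
      num_w <- (E(st$w + h * (seq_len(m) == j), st$b, st$c) -
                E(st$w - h * (seq_len(m) == j), st$b, st$c)) / (2 * h)
      num_b <- (E(st$w, st$b + h * (seq_len(m) == j), st$c) -
                E(st$w, st$b - h * (seq_len(m) == j), st$c)) / (2 * h)
      num_c <- (E(st$w, st$b, st$c + h * (seq_len(m) == j)) -
                E(st$w, st$b, st$c - h * (seq_len(m) == j))) / (2 * h)
      # relative to the gradient scale, with an absolute floor for the
      # near-zero components
      tol <- function(ref) 1e-6 * max(1, abs(ref))
      expect_lt(abs((upd$w[j] - st$w[j]) + st$eta * num_w), tol(num_w))
      expect_lt(abs((upd$b[j] - st$b[j]) + st$eta * num_b), tol(num_b))
      expect_lt(abs((upd$c[j] - st$c[j]) + st$eta * num_c), tol(num_c))
    }
  }
})

test_that("a matched network output is a fixed point of learning", {
  st <- rbf_state(m = 3, seed = 2, alpha = 0.05)
  fw <- rbf_forward(0.5, st)
  upd <- rbf_update(fw$u_rbf, fw$u_rbf, fw$h, 0.5, st)
  expect_equal(upd$w, st$w)
  expect_equal(upd$b, st$b)
  expect_equal(upd$c, st$c)
  # single node, unit activation, unit error: delta_w = eta
  st1 <- rbf_state(m = 1, centers = 0, widths = 5, seed = 1)
  fw1 <- rbf_forward(0, st1)
  upd1 <- rbf_update(fw1$u_rbf + 1, fw1$u_rbf, fw1$h, 0, st1)
  expect_equal(upd1$w - st1$w, 0.3)
})

test_that("widths never cross the positive floor", {
  st <- rbf_state(m = 2, centers = c(-1, 1), widths = 0.11, seed = 3,
                  width_floor = 0.1)
  st$w <- c(5, 5)
  for (i in 1:50) {
    fw <- rbf_forward(0.9, st)
    st <- rbf_update(fw$u_rbf + 10, fw$u_rbf, fw$h, 0.9, st)
  }
  expect_true(all(st$b >= 0.1))
})

test_that("command clamping is idempotent on [5, 200] Hz", {
  expect_equal(clamp_command(-3), 5)
  expect_equal(clamp_command(250), 200)
  expect_equal(clamp_command(77), 77)
  u <- stats::runif(100, -100, 400)
  expect_identical(clamp_command(clamp_command(u)), clamp_command(u))
  expect_true(all(clamp_command(u) >= 5 & clamp_command(u) <= 200))
})

test_that("the supervisory step clamps to the 5 Hz floor at zero error", {
  ctrl <- controller_spec("rbf_p", kp = 0.1)
  ctrl$rbf$w[] <- 0
  st <- supervisory_step(120, 120, 0.1, ctrl)
  expect_equal(st$sample$u_p, 0)
  expect_equal(st$sample$u_rbf, 0)
  expect_equal(st$sample$u, 5)
  expect_equal(st$sample$e, 0)
  # saturation at the ceiling
  ctrl2 <- controller_spec("rbf_p", kp = 0.1)
  ctrl2$rbf$w[] <- 50
  st2 <- supervisory_step(140, 120, 0.1, ctrl2)
  expect_equal(st2$sample$u, 200)
})

test_that("learning transfers the command from feedback to feedforward", {
  # frozen static plant: beta responds instantaneously to the command
  plant <- function(u) 124 - 0.05 * u
  y_d <- 119
  ctrl <- controller_spec("rbf_p", kp = 0.5)
  u <- 5
  up_hist <- E_hist <- numeric(120)
  for (i in 1:120) {
    st <- supervisory_step(plant(u), y_d, 0.1, ctrl)
    ctrl <- st$ctrl
    u <- st$sample$u
    up_hist[i] <- abs(st$sample$u_p)
    E_hist[i] <- 0.5 * (st$sample$u_rbf - st$sample$u)^2
  }
  # feedback term fades; the RBF carries the command
  expect_lt(mean(up_hist[100:120]), 0.1 * max(up_hist))
  expect_lt(mean(E_hist[100:120]), 0.05 * max(E_hist))
  expect_equal(plant(u), y_d, tolerance = 0.2)
})

test_that("zero learning rate and momentum freeze the RBF", {
  st <- rbf_state(m = 4, seed = 6)
  st$eta <- 1e-12  # the constructor requires eta in (0,1)
  st$alpha <- 0
  fw <- rbf_forward(1, st)
  upd <- rbf_update(fw$u_rbf + 5, fw$u_rbf, fw$h, 1, st)
  expect_equal(upd$w, st$w, tolerance = 1e-10)
  expect_equal(upd$b, st$b, tolerance = 1e-10)
  expect_equal(upd$c, st$c, tolerance = 1e-10)
})
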