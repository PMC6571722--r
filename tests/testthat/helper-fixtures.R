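# Shared fixtures: all generated in code, nothing stored on disk.

# grow a valid conformation bond-by-bond with shell-volume-uniform bonds and
# hard-sphere rejection -- an R-only generator independent of the compiled
# move code
random_conformation <- function(model, max_tries = 10000) {
  shell_r <- function() {
    u <- runif(1)
    (model$l_min^3 + u * (model$l_max^3 - model$l_min^3))^(1 / 3)
  }
  for (try in seq_len(max_tries)) {
    coords <- matrix(0, model$N, 3)
    ok <- TRUE
    for (m in 2:model$N) {
      z <- runif(1, -1, 1)
      phi <- runif(1, 0, 2 * pi)
      r <- shell_r()
      v <- r * c(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
      coords[m, ] <- coords[m - 1, ] + v
      if (!model$phantom && m > 2) {
        d2 <- rowSums((coords[1:(m - 2), , drop = FALSE] -
                       matrix(coords[m, ], m - 2, 3, byrow = TRUE))^2)
        if (any(d2 < model$sigma^2)) { ok <- FALSE; break }
      }
    }
    if (ok) return(coords)
  }
  stop("could not grow a valid conformation")
}

# brute-force all-pairs / all-angles contact count oracle in plain R
count_oracle <- function(coords, model) {
  n <- model$N
  nss <- nff <- nsf <- 0L
  if (!model$phantom) {
    for (i in 1:(n - 2)) for (j in (i + 2):n) {
      if (sum((coords[i, ] - coords[j, ])^2) <= model$R_cut^2) {
        ti <- model$types[i]; tj <- model$types[j]
        if (ti == 1 && tj == 1) nss <- nss + 1L
        else if (ti == 0 && tj == 0) nff <- nff + 1L
        else nsf <- nsf + 1L
      }
    }
  }
  nst <- 0L
  if (n >= 3) for (ctr in 2:(n - 1)) {
    if (!(model$types[ctr - 1] && model$types[ctr] && model$types[ctr + 1]))
      next
    a <- coords[ctr - 1, ] - coords[ctr, ]
    b <- coords[ctr + 1, ] - coords[ctr, ]
    cth <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    if (cth >= cos(model$theta_max * pi / 180) &&
        cth <= cos(model$theta_min * pi / 180))
      nst <- nst + 1L
  }
  list(nss = nss, nff = nff, nsf = nsf, nst = nst)
}

# proper random rotation + translation
rigid_motion <- function(coords) {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- rnorm(3, sd = 5)
  sweep(coords %*% R, 2, -shift)
}

# zig-zag chain whose interior valence angles all equal `angle_deg`:
# bond directions alternate +-(180 - angle)/2 about the x axis
zigzag_chain <- function(n, angle_deg, l = 1) {
  dev <- (180 - angle_deg) * pi / 180
  s <- rep_len(c(1, -1), n - 1)
  dirs <- cbind(cos(s * dev / 2), sin(s * dev / 2), 0)
  rbind(c(0, 0, 0), apply(dirs * l, 2, cumsum))
}

phantom_allS <- function(n, ...) {
  sf_model(N = n, b = n, pattern = rep("S", n), phantom = TRUE, ...)
}

# straight chain along x with spacing l
rod_chain <- function(n, l = 1) cbind((seq_len(n) - 1) * l, 0, 0)
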