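#' Analog Cauer (elliptic) low-pass prototype
#'
#' Designs the normalized analog elliptic low-pass prototype of order `n`
#' with at most `rp` dB passband ripple and at least `rs` dB stopband
#' attenuation, returned in zero-pole-gain form. The degree equation is
#' solved through the elliptic nome and the poles/zeros are evaluated with
#' Jacobi elliptic functions, the classical Cauer construction.
#'
#' @param n filter order (positive integer).
#' @param rp passband ripple in dB (> 0).
#' @param rs stopband attenuation in dB (> rp).
#' @return list with complex vectors `zero`, `pole` and numeric `gain`,
#'   compatible with [signal::sftrans()] / [signal::bilinear()].
#' @keywords internal
ellip_prototype <- function(n, rp, rs) {
  stopifnot(n == round(n), n >= 1, rp > 0, rs > rp)
  if (n == 1) {
    p <- -sqrt(1 / expm1(log(10) * 0.1 * rp))
    return(list(zero = complex(0), pole = as.complex(p), gain = -p))
  }
  eps_sq <- expm1(log(10) * 0.1 * rp)
  eps <- sqrt(eps_sq)
  ck1_sq <- eps_sq / expm1(log(10) * 0.1 * rs)

  K1 <- pracma::ellipke(ck1_sq)$k
  K1p <- pracma::ellipke(1 - ck1_sq)$k
  m <- .ellip_degree(n, ck1_sq, K1, K1p)
  capk <- pracma::ellipke(m)$k

  j <- seq(1 - n %% 2, n - 1, by = 2)
  ej <- pracma::ellipj(j * capk / n, m)
  s <- ej$sn; c_ <- ej$cn; d <- ej$dn

  snz <- s[abs(s) > 1e-12]
  z <- 1i / (sqrt(m) * snz)
  z <- c(z, Conj(z))

  r <- .arc_jac_sc1(1 / eps, ck1_sq)
  v0 <- capk * r / (n * K1)
  ev <- pracma::ellipj(v0, 1 - m)
  sv <- ev$sn; cv <- ev$cn; dv <- ev$dn
  p <- -(c_ * d * sv * cv + 1i * s * dv) / (1 - (d * sv)^2)

  if (n %% 2 == 1) {
    keep <- abs(Im(p)) > 1e-12 * sqrt(sum(Re(p * Conj(p))))
    p <- c(p, Conj(p[keep]))
  } else {
    p <- c(p, Conj(p))
  }
  g <- Re(prod(-p) / prod(-z))
  if (n %% 2 == 0) g <- g / sqrt(1 + eps_sq)
  list(zero = z, pole = p, gain = g)
}

# Solve n K(m)/K'(m) = K(m1)/K'(m1) for m via the nome expansion.
.ellip_degree <- function(n, m1, K1, K1p) {
  q1 <- exp(-pi * K1p / K1)
  q <- q1^(1 / n)
  kmax <- 7
  num <- sum(q^((0:kmax) * ((0:kmax) + 1)))
  den <- 1 + 2 * sum(q^((1:(kmax + 1))^2))
  16 * q * (num / den)^4
}

# Inverse Jacobi sn by descending Landen transformation; complex argument.
.arc_jac_sn <- function(w, m) {
  compl <- function(k) sqrt((1 - k) * (1 + k))
  k <- sqrt(m)
  if (k > 1) return(NaN)
  if (k == 1) return(atanh(w))
  ks <- k
  repeat {
    kp <- compl(ks[length(ks)])
    knext <- (1 - kp) / (1 + kp)
    ks <- c(ks, knext)
    if (knext == 0) break
    if (length(ks) > 12) stop_somnoage("Landen transformation not converging",
                                       class = "somnoage_filter_error")
  }
  K <- prod(1 + ks[-1]) * pi / 2
  wn <- w
  for (i in seq_len(length(ks) - 1)) {
    wn <- 2 * wn / ((1 + ks[i + 1]) * (1 + compl(ks[i] * wn)))
  }
  K * (2 / pi) * asin(wn)
}

# Real inverse sc with complementary modulus: solve w = sc(z, 1 - m).
.arc_jac_sc1 <- function(w, m) {
  z <- .arc_jac_sn(1i * w, m)
  if (abs(Re(z)) > 1e-10) stop_somnoage("inverse sc did not come out real",
                                        class = "somnoage_filter_error")
  Im(z)
}

#' Digital elliptic filter as second-order sections
#'
#' Designs an order-`n` digital elliptic filter (low/high/band-pass/stop)
#' and realizes it as cascaded biquads. Band transforms and the bilinear
#' discretization reuse [signal::sftrans()] and [signal::bilinear()];
#' poles and zeros are paired into sections nearest-pole-first so the
#' cascade stays numerically stable at high order.
#'
#' @param n prototype order.
#' @param rp,rs passband ripple / stopband attenuation in dB.
#' @param w critical frequency (or two-vector for band filters) as a
#'   fraction of the Nyquist frequency, inside (0, 1).
#' @param type one of `"low"`, `"high"`, `"pass"`, `"stop"`.
#' @return an object of class `somnoage_sos`: matrix with rows
#'   `(b0, b1, b2, a0, a1, a2)`.
#' @examples
#' sos <- ellip_sos(4, 1, 40, c(0.3, 45) / 64, "pass")
#' f <- seq(1, 40, by = 1)
#' round(abs(sos_freqz(sos, f, 128)), 2)
#' @export
ellip_sos <- function(n, rp, rs, w, type = c("low", "high", "pass", "stop")) {
  type <- match.arg(type)
  if (!all(w > 0 & w < 1)) {
    stop_somnoage("critical frequencies must lie strictly inside (0, 1) of Nyquist",
                  class = "somnoage_filter_error")
  }
  Tbl <- 2
  Wwarp <- 2 / Tbl * tan(pi * w / Tbl)
  zpg <- ellip_prototype(n, rp, rs)
  class(zpg) <- "Zpg"
  zpg <- signal::sftrans(zpg, W = Wwarp, stop = type %in% c("high", "stop"))
  zpg <- signal::bilinear(zpg, T = Tbl)
  if (any(abs(zpg$pole) >= 1)) {
    stop_somnoage("unstable realization: pole on or outside the unit circle",
                  class = "somnoage_filter_error")
  }
  sos <- .zpk2sos(zpg$zero, zpg$pole, zpg$gain)
  structure(sos, class = "somnoage_sos")
}

# Pair conjugate poles/zeros into biquads. Pole pairs closest to the unit
# circle are placed last and matched with the zero pair nearest in angle,
# which keeps intermediate section gains bounded.
.zpk2sos <- function(z, p, g) {
  pair_conj <- function(r) {
    if (length(r) == 0) return(list())
    r <- r[order(-abs(r), abs(Arg(r)))]
    used <- rep(FALSE, length(r))
    out <- list()
    for (i in seq_along(r)) {
      if (used[i]) next
      used[i] <- TRUE
      if (abs(Im(r[i])) < 1e-9 * max(1, abs(r[i]))) {
        j <- which(!used & abs(Im(r)) < 1e-9 * pmax(1, abs(r)))[1]
        if (!is.na(j)) {
          used[j] <- TRUE
          out[[length(out) + 1]] <- c(r[i], r[j])
        } else {
          out[[length(out) + 1]] <- r[i]
        }
      } else {
        cand <- which(!used)
        j <- cand[which.min(abs(r[cand] - Conj(r[i])))]
        used[j] <- TRUE
        out[[length(out) + 1]] <- c(r[i], r[j])
      }
    }
    out
  }
  poly_from_roots <- function(r) {
    pp <- 1
    for (ri in r) pp <- c(pp, 0) - c(0, pp * ri)
    Re(pp)
  }
  pp <- pair_conj(p)
  zz <- pair_conj(z)
  nsec <- max(length(pp), length(zz))
  sos <- matrix(0, nrow = nsec, ncol = 6)
  zused <- rep(FALSE, length(zz))
  for (k in seq_len(nsec)) {
    pk <- if (k <= length(pp)) pp[[k]] else complex(0)
    if (any(!zused)) {
      ang <- if (length(pk)) abs(Arg(pk[1])) else 0
      cand <- which(!zused)
      j <- cand[which.min(vapply(zz[cand],
                                 function(q) abs(abs(Arg(q[1])) - ang), 0))]
      zk <- zz[[j]]; zused[j] <- TRUE
    } else zk <- complex(0)
    b <- poly_from_roots(zk); a <- poly_from_roots(pk)
    b <- c(b, rep(0, 3 - length(b))); a <- c(a, rep(0, 3 - length(a)))
    sos[k, ] <- c(b, a)
  }
  # apply overall gain to the first section (last in application order is
  # nearest the unit circle; scaling the far-from-circle section is safest)
  sos <- sos[rev(seq_len(nsec)), , drop = FALSE]
  sos[1, 1:3] <- sos[1, 1:3] * g
  sos
}

#' Frequency response of a second-order-section cascade
#'
#' @param sos a `somnoage_sos` matrix.
#' @param f frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @return complex response at `f`.
#' @export
sos_freqz <- function(sos, f, fs) {
  w <- 2 * pi * f / fs
  ejw <- exp(-1i * w)
  H <- rep(1 + 0i, length(w))
  for (k in seq_len(nrow(sos))) {
    H <- H * (sos[k, 1] + sos[k, 2] * ejw + sos[k, 3] * ejw^2) /
      (sos[k, 4] + sos[k, 5] * ejw + sos[k, 6] * ejw^2)
  }
  H
}

# Single forward pass through the cascade (compiled).
sos_filter <- function(sos, x) {
  sos_filter_cpp(unclass(sos), as.numeric(x))
}

#' Zero-phase filtering through a second-order-section cascade
#'
#' Applies the cascade forwards and backwards so the net phase is zero.
#' Edge transients are suppressed by odd-reflection padding of
#' `3 * (2 * nrow(sos))` samples on both ends before filtering.
#'
#' @param sos a `somnoage_sos` matrix.
#' @param x numeric signal.
#' @return filtered signal, same length as `x`.
#' @export
sos_filtfilt <- function(sos, x) {
  n <- length(x)
  npad <- min(3 * 2 * nrow(sos), n - 1)
  if (npad > 0) {
    pre <- 2 * x[1] - x[seq(npad + 1, 2)]
    post <- 2 * x[n] - x[seq(n - 1, n - npad)]
    xp <- c(pre, x, post)
  } else xp <- x
  y <- sos_filter(sos, xp)
  y <- rev(sos_filter(sos, rev(y)))
  y[(npad + 1):(npad + n)]
}
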