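# Generated by data-raw/derive-series.py -- do not edit by hand.
# Truncated Taylor expansions about t = 1 (u = t - 1) of the
# guarded scalar functions; used when |t - 1| < .t_series_switch.

.ser_a <- function(u) {
  (1) + u * ((1.0/2.0) + u * ((-1.0/12.0) + u * ((1.0/24.0) + u * ((-19.0/720.0) + u * ((3.0/160.0) + u * (0))))))
}

.ser_b1 <- function(u) {
  (1.0/2.0) + u * ((1.0/3.0) + u * ((-1.0/24.0) + u * ((7.0/360.0) + u * ((-17.0/1440.0) + u * ((41.0/5040.0) + u * (0))))))
}

.ser_b2 <- function(u) {
  (1.0/2.0) + u * ((1.0/6.0) + u * ((-1.0/24.0) + u * ((1.0/45.0) + u * ((-7.0/480.0) + u * ((107.0/10080.0) + u * (0))))))
}

.ser_P <- function(u, alpha, beta) {
  (-1.0/2.0*alpha^2 + (1.0/2.0)*alpha + (1.0/2.0)*beta^2 - 1.0/2.0*beta) + u * ((-2.0/3.0*alpha^3 + alpha^2 - 5.0/12.0*alpha + (2.0/3.0)*beta^3 - beta^2 + (5.0/12.0)*beta) + u * ((-3.0/4.0*alpha^4 + (11.0/6.0)*alpha^3 - 35.0/24.0*alpha^2 + (5.0/12.0)*alpha + (3.0/4.0)*beta^4 - 11.0/6.0*beta^3 + (35.0/24.0)*beta^2 - 5.0/12.0*beta) + u * ((-4.0/5.0*alpha^5 + (11.0/4.0)*alpha^4 - 125.0/36.0*alpha^3 + (23.0/12.0)*alpha^2 - 17.0/40.0*alpha + (4.0/5.0)*beta^5 - 11.0/4.0*beta^4 + (125.0/36.0)*beta^3 - 23.0/12.0*beta^2 + (17.0/40.0)*beta) + u * ((-5.0/6.0*alpha^6 + (37.0/10.0)*alpha^5 - 311.0/48.0*alpha^4 + (67.0/12.0)*alpha^3 - 381.0/160.0*alpha^2 + (209.0/480.0)*alpha + (5.0/6.0)*beta^6 - 37.0/10.0*beta^5 + (311.0/48.0)*beta^4 - 67.0/12.0*beta^3 + (381.0/160.0)*beta^2 - 209.0/480.0*beta) + u * ((-6.0/7.0*alpha^7 + (14.0/3.0)*alpha^6 - 629.0/60.0*alpha^5 + (149.0/12.0)*alpha^4 - 1471.0/180.0*alpha^3 + (137.0/48.0)*alpha^2 - 8999.0/20160.0*alpha + (6.0/7.0)*beta^7 - 14.0/3.0*beta^6 + (629.0/60.0)*beta^5 - 149.0/12.0*beta^4 + (1471.0/180.0)*beta^3 - 137.0/48.0*beta^2 + (8999.0/20160.0)*beta) + u * (0))))))
}

.ser_Qt <- function(u, alpha, beta) {
  (-alpha + beta) + u * ((-alpha^2 + alpha + beta^2 - beta) + u * ((-alpha^3 + 2*alpha^2 - 13.0/12.0*alpha + beta^3 - 2*beta^2 + (13.0/12.0)*beta) + u * ((-alpha^4 + 3*alpha^3 - 37.0/12.0*alpha^2 + (7.0/6.0)*alpha + beta^4 - 3*beta^3 + (37.0/12.0)*beta^2 - 7.0/6.0*beta) + u * ((-alpha^5 + 4*alpha^4 - 73.0/12.0*alpha^3 + (17.0/4.0)*alpha^2 - 299.0/240.0*alpha + beta^5 - 4*beta^4 + (73.0/12.0)*beta^3 - 17.0/4.0*beta^2 + (299.0/240.0)*beta) + u * ((-alpha^6 + 5*alpha^5 - 121.0/12.0*alpha^4 + (31.0/3.0)*alpha^3 - 1319.0/240.0*alpha^2 + (317.0/240.0)*alpha + beta^6 - 5*beta^5 + (121.0/12.0)*beta^4 - 31.0/3.0*beta^3 + (1319.0/240.0)*beta^2 - 317.0/240.0*beta) + u * (0))))))
}
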