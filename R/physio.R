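# Photosynthetic physiology: electrolyte leakage, chlorophyll content,
# light-response fitting, and the PPPI / RNAT / CDRI indices.

# Fixed loadings of the three physiological parameters on the principal
# components, and the variance-contribution weights used to combine the
# component scores into the PPPI. These are constants of the method.
PPPI_LOADINGS <- matrix(
  c( 0.548,  0.830, 0.105,   # P_max
    -0.596,  0.300, 0.745,   # REC
     0.586, -0.471, 0.659),  # Chl_a+b
  nrow = 3, byrow = TRUE,
  dimnames = list(c("P_max", "REC", "Chl_a+b"), c("PC1", "PC2", "PC3")))
PPPI_WEIGHTS   <- c(PC1 = 0.507, PC2 = 0.259, PC3 = 0.234)
PPPI_INTERCEPT <- -5
CDRI_DIVISOR   <- 650

#' Relative electrolyte conductivity
#'
#' REC = C1/C2, the conductivity of the leaf-fragment bath before boiling
#' relative to the conductivity after boiling (total electrolyte release).
#' An REC near 1 means the membranes were already fully leaky before
#' boiling, i.e. severe tissue damage.
#'
#' @param C1 Conductivity before boiling (uS/cm), 0 <= C1 <= C2.
#' @param C2 Conductivity after boiling (uS/cm), > 0.
#' @return REC in (0, 1], dimensionless.
#' @examples
#' rec(36.8, 200) # control-level leakage, 0.184
#' @export
rec <- function(C1, C2) {
  stopifnot(is.numeric(C1), is.numeric(C2), length(C1) == length(C2))
  if (any(!is.finite(C1)) || any(!is.finite(C2)) || any(C2 <= 0) || any(C1 < 0))
    cp_stop("rec(): C2 must be > 0 and C1 >= 0 and finite")
  if (any(C1 > C2))
    cp_stop("rec(): C1 > C2 (boiling must not lower conductivity)")
  C1 / C2
}

#' Total chlorophyll content from ethanol-extract absorbances
#'
#' Concentrations (mg/L) from the two-wavelength equations
#' `c_a = 13.95 A665 - 6.88 A649`, `c_b = 24.96 A649 - 7.32 A665`;
#' the content per gram fresh weight is
#' `C_ab = (c_a + c_b) * (V/1000) * D / m` with V in mL so that the usual
#' bench values (V = 25 mL, m = 0.2 g) give mg per gram.
#'
#' @param A649,A665 Absorbances at 649 and 665 nm (>= 0).
#' @param V_mL Extract volume in mL (default 25).
#' @param D Dilution factor (default 1).
#' @param m_g Sample fresh weight in g (default 0.2).
#' @return Total chlorophyll content in mg g^-1.
#' @examples
#' chlorophyll(1, 1) # 3.08875 mg/g
#' @export
chlorophyll <- function(A649, A665, V_mL = 25, D = 1, m_g = 0.2) {
  stopifnot(is.numeric(A649), is.numeric(A665))
  if (any(A649 < 0) || any(A665 < 0) || m_g <= 0 || V_mL <= 0 || D <= 0)
    cp_stop("chlorophyll(): absorbances must be >= 0 and V, D, m > 0")
  c_a <- 13.95 * A665 - 6.88 * A649
  c_b <- 24.96 * A649 - 7.32 * A665
  if (any(c_a < 0) || any(c_b < 0))
    cp_stop("chlorophyll(): inconsistent absorbances (negative pigment concentration)")
  (c_a + c_b) * (V_mL / 1000) * D / m_g
}

#' Fit a light-response curve and extract the maximum net photosynthetic rate
#'
#' Fits the modified rectangular hyperbola
#' `Pn(I) = alpha * (1 - beta*I) / (1 + gamma*I) * I - Rd`
#' by least squares. P_max is evaluated at the analytic optimum irradiance
#' `I_opt = (sqrt((beta+gamma)/beta) - 1) / gamma`; if the optimum falls
#' outside the measured irradiance range (e.g. a purely saturating curve),
#' the fitted plateau maximum over the measured range is reported instead.
#'
#' @param I Irradiance values (umol m^-2 s^-1), must include 0.
#' @param Pn Net photosynthetic rates at `I`.
#' @param model `"mrh"` (modified rectangular hyperbola, default) or
#'   `"rh"` (rectangular hyperbola, i.e. beta fixed at 0).
#' @return An object of class `light_response_fit` with elements `alpha`,
#'   `beta`, `gamma`, `Rd`, `p_max`, `i_opt`, `sse`, `fitted`.
#' @export
fit_light_response <- function(I, Pn, model = c("mrh", "rh")) {
  model <- match.arg(model)
  stopifnot(length(I) == length(Pn))
  if (length(I) < 6 || !any(I == 0))
    cp_stop("fit_light_response(): need >= 6 points including I = 0")
  if (all(abs(Pn) < 1e-12))
    cp_stop("fit_light_response(): degenerate all-zero light response")
  ord <- order(I); I <- I[ord]; Pn <- Pn[ord]

  pred <- function(par, i) {
    a <- exp(par[1]); b <- if (model == "mrh") exp(par[2]) else 0
    g <- exp(par[3]); rd <- par[4]
    a * (1 - b * i) / (1 + g * i) * i - rd
  }
  sse <- function(par) {
    r <- Pn - pred(par, I)
    if (any(!is.finite(r))) return(1e18)
    sum(r^2)
  }
  # start values: slope from the low-light points, plateau-derived gamma
  lo <- I > 0 & I <= 220
  a0 <- max(1e-3, stats::coef(stats::lm(Pn[I <= 220] ~ I[I <= 220]))[2])
  rd0 <- -Pn[I == 0][1]
  p0 <- log(c(a0, 3e-4, 1.5e-3)); p0[4] <- rd0
  fit <- stats::optim(p0, sse, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  fit <- stats::optim(fit$par, sse, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  if (!is.finite(fit$value))
    cp_stop("fit_light_response(): non-convergence (sse = %g)", fit$value)
  alpha <- exp(fit$par[1])
  beta  <- if (model == "mrh") exp(fit$par[2]) else 0
  gamma <- exp(fit$par[3]); Rd <- fit$par[4]

  if (beta > 1e-12) {
    i_opt <- (sqrt((beta + gamma) / beta) - 1) / gamma
  } else {
    i_opt <- Inf
  }
  if (is.finite(i_opt) && i_opt <= max(I) && i_opt >= min(I)) {
    p_max <- alpha * (1 - beta * i_opt) / (1 + gamma * i_opt) * i_opt - Rd
  } else {
    # saturating curve: plateau value over the measured range
    grid <- seq(min(I), max(I), length.out = 2048)
    p_max <- max(pred(fit$par, grid))
    i_opt <- grid[which.max(pred(fit$par, grid))]
  }
  if (p_max < max(Pn) - 0.05 * max(abs(Pn)))
    cp_log("fit_light_response: fitted P_max %.3f below observed max Pn %.3f",
           p_max, max(Pn))
  structure(list(model = model, alpha = alpha, beta = beta, gamma = gamma,
                 Rd = Rd, p_max = p_max, i_opt = i_opt, sse = fit$value,
                 fitted = pred(fit$par, I)),
            class = "light_response_fit")
}

#' @export
print.light_response_fit <- function(x, ...) {
  cat(sprintf("Light-response fit (%s): P_max = %.3f at I = %.0f; Rd = %.3f; SSE = %.3g\n",
              x$model, x$p_max, x$i_opt, x$Rd, x$sse))
  invisible(x)
}

#' Photosynthetic Physiological Potential Index
#'
#' Fixed linear combination of the raw physiological parameters. Component
#' scores `S_k` are the loadings applied to (P_max, REC, Chl_a+b); the PPPI
#' is their variance-contribution-weighted sum minus 5:
#' `PPPI = 0.507 S1 + 0.259 S2 + 0.234 S3 - 5`.
#'
#' @param p_max Maximum net photosynthetic rate (umol m^-2 s^-1).
#' @param rec Relative electrolyte conductivity (0-1).
#' @param chl Total chlorophyll content (mg g^-1).
#' @return PPPI value(s); ~4.5 for unstressed control plants, near 0 under
#'   severe cold damage.
#' @examples
#' pppi(16.598, 0.184, 2.933) # control level, ~4.545
#' @export
pppi <- function(p_max, rec, chl) {
  stopifnot(is.numeric(p_max), is.numeric(rec), is.numeric(chl))
  s <- cbind(p_max, rec, chl) %*% PPPI_LOADINGS
  drop(s %*% PPPI_WEIGHTS) + PPPI_INTERCEPT
}

#' Relative negative accumulated temperature
#'
#' Hourly sum of (control temperature - treatment temperature) over the
#' stress period, in degree-hours. Zero for the control against itself;
#' grows with both the depth and the duration of cooling.
#'
#' @param profile_ck,profile_lt Hourly temperature profiles
#'   ([temperature_profile] objects or plain numeric vectors) of equal length.
#' @return RNAT in degC h.
#' @export
rnat <- function(profile_ck, profile_lt) {
  t_ck <- if (inherits(profile_ck, "temperature_profile")) profile_ck$hourly_c else profile_ck
  t_lt <- if (inherits(profile_lt, "temperature_profile")) profile_lt$hourly_c else profile_lt
  if (length(t_ck) != length(t_lt))
    cp_stop("rnat(): profile length mismatch (%d vs %d)", length(t_ck), length(t_lt))
  sum(t_ck - t_lt)
}

#' Cold damage risk index and discrete risk level
#'
#' `CDRI = PPPI - RNAT/650`. Risk levels (left-closed, right-open bands):
#' level 0 (no risk) for CDRI >= 3; levels 1-3 (blue / yellow / red warning)
#' for CDRI in [2,3), [1,2), [0,1); level 4 (damage occurred) for CDRI < 0.
#'
#' @param pppi_value PPPI value(s).
#' @param rnat_value RNAT value(s) in degC h, >= 0.
#' @return A data.frame with columns `rnat`, `cdri`, `level`.
#' @examples
#' cdri(4.545, 0)      # control: level 0
#' cdri(0.142, 3240)   # severe stress: level 4
#' @export
cdri <- function(pppi_value, rnat_value) {
  stopifnot(is.numeric(pppi_value), is.numeric(rnat_value))
  if (any(rnat_value < 0))
    cp_stop("cdri(): rnat must be >= 0")
  val <- pppi_value - rnat_value / CDRI_DIVISOR
  data.frame(rnat = rnat_value, cdri = val, level = risk_level(val))
}

#' Discretize CDRI values into the five risk levels
#' @param cdri_value Numeric CDRI value(s).
#' @return Integer level(s) 0-4.
#' @export
risk_level <- function(cdri_value) {
  lv <- integer(length(cdri_value))
  lv[cdri_value >= 3] <- 0L
  lv[cdri_value >= 2 & cdri_value < 3] <- 1L
  lv[cdri_value >= 1 & cdri_value < 2] <- 2L
  lv[cdri_value >= 0 & cdri_value < 1] <- 3L
  lv[cdri_value < 0] <- 4L
  lv
}
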