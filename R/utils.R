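# internal helpers shared across modules

# round half away from zero, to match conventional reporting of percentages
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(structure(class = c("bipolaRF_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_binary <- function(y, what = "outcome") {
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop_input(what, " must be coded 0/1 with no missing values")
  y
}

# canonical predictor order used throughout the package
RF_PREDICTORS <- c("rf_power", "init_impedance", "rf_duration",
                   "imp_drop5", "pct_imp_drop5", "thickness")

# numerically stable log(1 + exp(x))
log1pexp <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
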