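# Shared fixtures: built once per test run, in code.

crv_m <- synthetic_reference("male")
crv_f <- synthetic_reference("female")
subj_m <- subject("male")
subj_f <- subject("female")
PARAMS <- model_params()

# adult male state at a given body weight, composition on the indicated FMI
adult_state <- function(bw = 80, age_years = 30, curves = crv_m,
                        subj = subj_m, params = PARAMS) {
  a <- yr(age_years)
  h <- indicated_height(curves, subj, a)
  bmi <- bw / h^2
  fmi <- indicated_fmi(bmi, curves$bmi_ref(a), curves$fmi_ref(a), subj, a,
                       params$comp)
  body_state(fm = fmi * h^2, ffm = (bmi - fmi) * h^2, h = h, age = a)
}

# write a small LMS CSV (synthetic values) and return its path
write_lms_fixture <- function(dir = tempdir(), median_col = "M") {
  path <- file.path(dir, paste0("lms_", median_col, ".csv"))
  age <- c(0, 182, 365, 730, 1461, 2922, 5844, 7305)
  med <- c(0.50, 0.67, 0.75, 0.87, 1.02, 1.27, 1.62, 1.77)
  tab <- if (median_col == "M") {
    data.frame(age_days = age, L = 1, M = med, S = 0.035)
  } else {
    data.frame(age_days = age, P50 = med)
  }
  utils::write.csv(tab, path, row.names = FALSE)
  path
}
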