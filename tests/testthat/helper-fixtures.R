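# Two fixed fixtures with reference values frozen from an independent GEE
# implementation (statsmodels 0.14, gaussian family, exchangeable working
# correlation, moment estimators with N - p / N* - p denominators).

fixture_balanced <- data.frame(
  patient_id = rep(c("A", "B", "C", "D"), each = 2),
  dr_stage   = c(0, 0, 2, 2, 1, 1, 4, 4),
  fd         = c(8.4, 9.0, 10.9, 10.4, 9.1, 8.8, 12.6, 12.1))

ref_balanced <- list(
  beta      = c(8.46, 0.972857142857143),
  robust_se = c(0.245819578768900, 0.063763593988800),
  model_se  = c(0.275194736245000, 0.120104829495000),
  alpha     = 0.288118090147006,
  phi       = 0.195976190476190,
  qic       = 8.514241282804782)

fixture_unbalanced <- data.frame(
  patient_id = c(1, 1, 2, 3, 4, 4, 5, 6, 6, 7, 7, 8, 8, 9, 9, 10, 10, 11,
                 12, 13, 13, 14, 15, 16, 17, 17, 18, 18, 19, 19, 20, 20),
  age_years  = c(68, 68, 65, 65, 58, 58, 55, 56, 56, 45, 45, 38, 38, 57, 57,
                 65, 65, 52, 43, 46, 46, 38, 48, 40, 60, 60, 58, 58, 57, 57,
                 41, 41),
  dr_stage   = c(0, 0, 0, 4, 1, 1, 2, 2, 2, 2, 2, 3, 3, 1, 1, 4, 4, 2, 0, 2,
                 2, 4, 2, 2, 4, 4, 1, 1, 3, 3, 1, 1),
  fd         = c(10.21, 9.53, 10.61, 11.31, 8.09, 8.88, 6.74, 9.82, 9.82,
                 11.61, 11.64, 8.69, 6.69, 9.48, 9.40, 13.57, 11.86, 9.74,
                 6.93, 8.22, 9.27, 11.05, 10.56, 7.22, 11.73, 11.42, 10.71,
                 11.32, 8.32, 11.49, 6.88, 9.15))

ref_unbalanced <- list(
  beta      = c(3.654387966644621, 0.091742354768411, 0.593351865365821),
  robust_se = c(1.392025816232343, 0.024775488369276, 0.132819440591899),
  model_se  = c(1.667478024714296, 0.029473655346580, 0.215395493934312),
  alpha     = 0.394296284075111,
  phi       = 1.934098349482515,
  qic       = 34.035572275350823)
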