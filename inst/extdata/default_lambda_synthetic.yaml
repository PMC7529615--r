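# SYNTHETIC class-conditional categorical parameters (lambda) for the cohort
# generator.  These numbers are invented configuration, chosen only to satisfy
# the qualitative class contrasts the analysis expects:
#   - class 2 (severe histology, or CD) puts more mass on abnormal levels
#     (k > 1) than class 1 for every feature except f8 (ulcers), where the two
#     classes are nearly identical and the abnormal level is rare;
#   - class 1 of the disease task (SNVA) favours the patchy level of f2
#     relative to continuous, while CD favours continuous.
# They are NOT estimates from any patient cohort.
severity:
  class1:            # mild histology (Marsh 0/1/2)
    f1: [0.70, 0.30]
    f2: [0.70, 0.18, 0.12]
    f3: [0.65, 0.35]
    f4: [0.60, 0.40]
    f5: [0.70, 0.30]
    f6: [0.85, 0.15]
    f7: [0.88, 0.12]
    f8: [0.97, 0.03]
    f9: [0.90, 0.10]
  class2:            # severe histology (Marsh 3a/3b/3c)
    f1: [0.25, 0.75]
    f2: [0.25, 0.15, 0.60]
    f3: [0.35, 0.65]
    f4: [0.30, 0.70]
    f5: [0.40, 0.60]
    f6: [0.65, 0.35]
    f7: [0.70, 0.30]
    f8: [0.96, 0.04]
    f9: [0.70, 0.30]
disease:
  class1:            # SNVA
    f1: [0.60, 0.40]
    f2: [0.50, 0.35, 0.15]
    f3: [0.60, 0.40]
    f4: [0.55, 0.45]
    f5: [0.65, 0.35]
    f6: [0.80, 0.20]
    f7: [0.85, 0.15]
    f8: [0.97, 0.03]
    f9: [0.85, 0.15]
  class2:            # CD
    f1: [0.30, 0.70]
    f2: [0.25, 0.10, 0.65]
    f3: [0.35, 0.65]
    f4: [0.30, 0.70]
    f5: [0.40, 0.60]
    f6: [0.70, 0.30]
    f7: [0.75, 0.25]
    f8: [0.96, 0.04]
    f9: [0.70, 0.30]
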