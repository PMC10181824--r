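# Amyloid / tau positivity cut-offs, version 1.
# modality: which measurement defines amyloid status in each cohort.
#   csf  -> CSF amyloid-beta 42, pg/mL; values BELOW the cut-off are A+
#   pet  -> amyloid PET Centiloids; values ABOVE the cut-off are A+
# ptau_cutoff: CSF p-tau181, pg/mL; values ABOVE the cut-off are T+
# Values exactly at a cut-off are classified normal (strict inequality).
version: 1
cohorts:
  "ALFA+":
    modality: csf
    abeta_cutoff: 1098
    ptau_cutoff: 24
  "EPAD":
    modality: csf
    abeta_cutoff: 1098
    ptau_cutoff: 24
  "ADNI":
    modality: csf
    abeta_cutoff: 880
    ptau_cutoff: 24
  "OASIS":
    modality: pet
    abeta_cutoff: 17
    ptau_cutoff: 24
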