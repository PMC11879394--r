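# Example MC-ISM pipeline run: simulate a bead field, OLID-filter,
# localize the spot lattice and reconstruct by pixel reassignment.
schema_version: 1
seed: 1

optics:
  lambda_ex: 640        # nm
  lambda_em: 680        # nm
  na: 1.49
  pixel_nm: 32.5

geometry:
  diameter_au: 0.5      # pinhole diameter at the sample plane
  pitch_ratio: 3        # 1:3 diameter:pitch
  frames_per_side: 5    # tilt = arctan(1/5)

trajectory:
  n_frames: 25
  step_au: 0.3467       # 0.25 AU enlarged by the 49->25 factor 1.39

simulate:
  phantom:
    kind: plate
  dim: 96
  noise:
    snr_db: 20
    kind: gaussian

olid:
  dc_attenuation: 0.0

locate:
  method: detect

reconstruct:
  method: pr
  sigma_rel: 1.0
  upsample: 2

metrics:
  enabled: true
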