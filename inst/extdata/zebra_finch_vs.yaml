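# Zebra finch-like tetrachromatic visual system.
#
# Pigment peaks and oil-droplet cut-offs are approximate literature values
# for the zebra finch (UVS-type SWS1 retina); they are configuration data,
# not measurements made by this package. The ocular media entry "default"
# selects the package's synthetic logistic transmittance template.
# The UVS cone has an unpigmented (transparent) droplet, hence no lambda_cut.

cones:
  UVS:
    lambda_max: 359
  SWS:
    lambda_max: 430
    lambda_cut: 420
    slope: 0.08
  MWS:
    lambda_max: 505
    lambda_cut: 505
    slope: 0.08
  LWS:
    lambda_max: 565
    lambda_cut: 560
    slope: 0.08

# Double cone: LWS pigment behind a pale (P-type) droplet; achromatic channel.
double_cone:
  lambda_max: 565
  lambda_cut: 415
  slope: 0.05

ocular: default

# Receptor noise: Weber fraction of the LWS mechanism and relative cone
# abundances per receptive field (UVS : SWS : MWS : LWS).
weber_lws: 0.1
abundances:
  UVS: 1
  SWS: 1.5
  MWS: 2
  LWS: 3
noise_scaling: sqrt
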