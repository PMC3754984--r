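# spr-stack v1
wavelength_nm: 670
angle_offset_deg: 2.1600000000000001
layer: prism 1.5294000000000001 0 inf
layer: chromium 3.1084999999999998 3.4872999999999998 1.53
layer: gold 0.22620000000000001 3.7639 50.590000000000003
layer: sample 1.45 0 10
layer: bulk 1.3299000000000001 0 inf
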