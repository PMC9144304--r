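tricin_synthetic
  driftanchor

  0  0  0  0  0  0  0  0  0  0999 V2000
M  END
> <NAME>
tricin_synthetic

> <ACCESSION>
SYN-FIO-0001

> <MASS SPECTRAL PEAKS>
100.0 20000
250.0 40000

$$$$
apigenin_synthetic
  driftanchor

  0  0  0  0  0  0  0  0  0  0999 V2000
M  END
> <NAME>
apigenin_synthetic

> <ACCESSION>
SYN-FIO-0002

> <MASS SPECTRAL PEAKS>
100.0 6000
250.0 12000

$$$$
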