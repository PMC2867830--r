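Place the deposited genome sequences here to enable the full in-silico
PCR validation of the polyketide-operon deletion:

  AP011541.fa   B. subtilis natto BEST195 chromosome (DDBJ AP011541)
  AL009126.fa   B. subtilis Marburg 168 chromosome (EMBL/DDBJ AL009126)

Both are a few megabases and are therefore not shipped with the package.
With the files in place, the acceptance test predicts the A+B and C+D
products (~3.14 kb and ~3.10 kb) on the 168 chromosome and the A+D
product (~1.62 kb) on the BEST195 chromosome.
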