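# Fructose tolerance screen over three causal ALDOB variants.
# Homozygous at any site: intolerant; heterozygous at any site: carrier.
Any
rs1800546 'GG'
rs76917243 'TT'
rs78340951 'CC'
== "Fructose Intolerant"

Any:
rs1800546 'C/G'
rs76917243 'G/T'
rs78340951 C/G
== "Variant Carrier"

else "Tolerant to Fructose"
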