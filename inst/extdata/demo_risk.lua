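if rs568149713 == "A/G"
and rs557514207 == "G/G" then

   comment = "highrisk"

   risk = 0.8

end

if chr1:16949 == "A/C"
or rs553090414 == "C/C"
then

   comment = "mediumrisk"

   risk = 0.5

end
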