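>sp|Q9H3Z4|DNJC5_HUMAN DnaJ homolog subfamily C member 5 (CSPalpha), 198 aa
MADQRQRSLSTSGESLYHVLGLDKNATSDDIKKSYRKLALKYHPDKNPDNPEAADKFKEI
NNAHAILTDATKRNIYDKYGSLGLYVAEQFGEENVNTYFVLSSWWAKALFVFCGLLTCCY
CCCCLCCCFNCCCGKCKPKAPEGEETEFYVSPEDLEAQLQSDEREATDTPIVIQPASATE
TTQLTADSHPSYHTDGFN
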