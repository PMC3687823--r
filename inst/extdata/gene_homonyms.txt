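WAS
SET
MET
CAT
REST
IMPACT
AIM
MICE
COPE
SHE
ITCH
PIGS
FATE
CLOCK
ACT
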