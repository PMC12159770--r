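agent_id,score
amoxicillin,3
amoxicillin_clavulanate,5
ampicillin,3
ampicillin_sulbactam,5.5
azithromycin,4
aztreonam,5
cefazolin,3
cefepime,8
ceftriaxone,6
ciprofloxacin,6.5
clindamycin,4
daptomycin,4.5
doxycycline,5
ertapenem,8.5
levofloxacin,7
linezolid,4.5
meropenem,11
metronidazole,2
piperacillin_tazobactam,10
trimethoprim_sulfamethoxazole,5
vancomycin_iv,4
vancomycin_po,1
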