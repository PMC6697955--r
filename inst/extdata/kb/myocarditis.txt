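Myocarditis is inflammation of the heart muscle, the myocardium. Symptoms can include chest pain, shortness of breath, and an irregular heartbeat. Myocarditis most often results from a viral infection that reaches the heart, and it can reduce the ability of the heart to pump blood.
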