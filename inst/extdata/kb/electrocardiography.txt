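Electrocardiography is the process of producing an electrocardiogram, a recording of the heart's electrical activity through repeated cardiac cycles. It is an electrogram of the heart, a graph of voltage versus time of the electrical activity of the heart using electrodes placed on the skin. These electrodes detect the small electrical changes that are a consequence of cardiac muscle depolarization followed by repolarization during each cardiac cycle. Changes in the normal pattern occur in numerous cardiac abnormalities. In a conventional 12-lead recording, ten electrodes are placed on the chest, across the thorax, and on the limbs.
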