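>H3 S. cerevisiae histone H3 (HHT1), mature chain (initiator Met removed)
ARTKQTARKSTGGKAPRKQLASKAARKSAPSTGGVKKPHRYKPGTVALREIRRFQKSTEL
LIRKLPFQRLVREIAQDFKTDLRFQSSAIGALQESVEAYLVSLFEDTNLAAIHAKRVTIQ
KKDIKLARRLRGERS
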