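>syn001
MQTDDKDDCYTNNAPGSLMYYIIYGHLLKNYHDKDLYCAPSQNVRYTNCKLFQLVRFDMLLHYTIYLEEV
KNPVIFIGWVSHRDLGRFMGCYEKPMDHRWSVGAQMMQPITFFYKIPHQAYRMSFFNMYGTFQECWDANA
YQEQGCRDGFAYLHSQSRALYSAVGMRIADANRFWAYLNWKFSTSINHGFKSGEQIINSWTAMETKDMAR
RKSGLPQKMWQYHRPRIKEQEDKEDERWWN
>syn002
MQTRDKDDCYTNNAPGSLMYYIIYGHLLKNYHDKDLYCAPSQNVRYTNCKLFQCVRFDMFLHYTYYLEEW
KHPVYFIGWFSHRVWGRFMGCYEKPMDHRWNVIAQMMQPITFFYKTPHQLYRMSPFNMYATFQIKWDANL
YPKQACQDGPAYLPSQSRALYSAVGMRIAPANRFWAYLQGKNSTTICHGFKSGEQIINSGTAMESHDMAR
RKSGLPQKMWQYHRPRIKEVEDKEDERWWN
>syn003
MQTDDKEDCYDNNAPGSLMYYIAYGHLLKNYHDKDLYCAPSQNVRYTNCKLFQCVRFDMWLHYTFYLEEY
KNPVFFIGWWWHRDYGRFMGCYEKPMDHRWSVGAQMMQPIHFFYKIPHQHYRMSKFNMYRTFQIKWDANH
YQEQRCRDGKAYLPSQSRALYSAVGMRIAPLNRFWAYLNDKFSTEINHGFKSGEQIINSEWEMEDHDMAR
RKSGLPQKMWQYHMPPIKEQEDKEDERWWN
>syn004
MQTDDKDDCVTNNAPGWLMYYIIYGHLLKNYHDKDLYCEPSQNVRYTNCKLFQCVRFDMYLHYTFYLEEW
KNPVFFITWYSHRDWGRFMCDYEKPMDHRWSVGAQTMQPITFFYKIPHQSYRMSTFNMYNTQQIKWDANS
YQEQTCRDGNAYLPSQSRALYCAVGMRIAPANRFWAYLNQKFSTHIPHGFKSGEQIINSQTAMEGHDMAR
RKSGLPQKMWQYHRIRIVEQEDKEDERWIN
>syn005
MQTDDKDDCYNNNAPGSLMYEIIYGHQLKNYHDKDLYCAPSQNVRYTNCKLRQCVRFDMASHYNGYLELS
KNPVGFIGWASHEDSGRFMGCYEKPMDHRWSVGAQMMQPITFFYKIPHQTLRMSVFNMYLTFQIKDDANT
YQEQVCTDGLAYLPSQSRALYSAVGMRIASANRFWAYLNIKFSTCINHWFKSGEQIINSITAMECHDMAR
RKSGLPQKMWDYHDPRIKEQEDKEDERWWN
>syn006
MQTDDKDDCYTNNACGSTMYYIIYGHLLKNYHDKPLYCAPSQNVRYTNCKLFQCVRFDMEQHYTDYLEEQ
KNPVDFIGWESHRDQGRFMGCYEKPMDHRWSVGAQMMQPDTFFKKIPHKNYRMRKFNMYRTFQIKWDANN
YQEQRCRDGKAYLPSQSRALYSAVGMRIAPANRFVAYLNHKFSTSIKHGFKSGIQGINSHTAMETHDMAR
RKSGLPQKMWQYHRPRIKEQEDKEDERWWN
>syn007
MQTDDKDDCYTNNAPGELMYYIIYLHLEKNYHDKDLYCAPSQNVRYTNCKLFQCVRFDMCLHWTSYLEET
KNPVSFIGWCSHRVTDRFMGCYEEPMDHRWSVGAQMKQPITFFYKYPHQAYRMSGFNMYPTFFIQWPANA
YQEQGCRDGPAYLPSQSRALSFAVMMRIAPANRFWAYLNVKFSTMIAHGFKSGEQIINSVPGQEMHDMAR
RKSGLPQKMWQYHRPMIKEQEDKEDERWWN
>syn008
MQTDDKDDCYTNNACGSLMYYIIYGHLLKNYHDKDLYCAPDQNVEYTNCKLFQCVRFDMSIHYTTYLEEN
KNPVTFIGWSSHRDNGRFMGCYEKPMDHRWSVGAQMMIPITFFYKIPHKQYRMSAFNMYGTFQIKWDANQ
YQEQACRDGGAYFPSQSRELYSAVLMRIAPANRFWAYLNCKFSTYINHGFKSGEQIINSCTAMEWHDMAR
RKNGLPQKMWQYHRPRAKEQEDKEDERWWN
>syn009
MQTDDKDDCYTNNAWGSLMYYIIYGHFLKNYHDKDLYCAPSQNVRYTNCKLFQCVNFDMPLHYTGYLEEA
KNPVGFIGWPSHRDAGRFMGCYEKPMDHRWSVGAQMMQPITFFYKIPHQVYRMSLFNMYSTFQIKLDANV
YVEQLCRDDSAYLPSQSRALYSAVGMRIAPANRFWAYYNTKFSTFWNHGFKSGEQIINSTTAMEYHDMAR
RKSGLPQKMYQYHRPRIKEQEDKIDERSWN
>syn010
MQTDDKDDCYTNNDPGSLMHYIWPGHLLKNYHDKDLYCAPSQNVWYTNCKLFPCVRFDMKLHYTRYLEEH
KNPYRFSGWKSHADHFRFMGCYEKPMDHRWSVGAQMMQPITFFYKIPHQEYRMSDFNMYQTFQIKWDANE
YQEQDCRDGQAYLPSQSRALYSAVGMRIAPANRFWACLNNKFSTSYNHGFKSGEQIITSNTALETHGMAR
RKSGLPQKMWQYHRPRIKEQEDKEDERWWN
>syn011
MYTDDKDLCYTNNAPGSLMYYIIYGHLLKNYHDKDLYCAPSQNVRYTNCKLFQCVRFDMVLHYTIYLEEL
KNPVIFIGWVSHRDLIRFMGCYEKPMDHRWSVGAQMMQPRDFFSKIPHQAYRRFMFNMYGTFQIKWDANA
YQEQMCRDGGAYLPSQSRALYSAVGMRIAPANRFWAYLNSKFSITINHGFKSGEQIINSSTAMECHDMAR
RKSGLPQKMWQYHRPRIKEQEDKEDERWWN
>syn012
MQTDDKDDCYTNNAPGSLMYYIIYGHLLKNYHQKDLYCAPSQNVRYTNCKLFQCVRFDMGLHYTAYLEES
KNPVAFIGWGSHRDSGFFMGCYEKPMDHRWSVGAQMMQPITFFYKIPHQPYSMSVFNMYCTFQIKWDANP
YQEQVCRDGCAYLPSQSRALYSAVGMRIADANQKWAYLNTKFSTNINHGFKSGEQIINSTTAMEQHDMAR
RKSGLPQKMWQYHRPRIKEQEDKEDERWWN
>syn013
MQTDDKDDCCTNTRPGSLMYRIIYGHSLKNYHDKDLYCAPSQNVRYTNCKLFQCVRFDMLLHYTIYLEEV
KNPVIFIGWVPHRDLGRFMGCYEKRRDHRWSVGAQMMQPHVFFYKIPHQAYRMSFFNMYGTFQIKWDANA
YQEQGCRDGFAYLPSQSRALKSARCTRIAPANRFWAYLNWKFSTSINHGFKSGEQIINSWTMMETHDMAR
RKSGLQQKMWQYHRPRIKEQEDKYDERWWN
>syn014
MKTKDKDTCYTQNATCSLTYQIIMGHLLKAYPDLDFYSMPSQNVRVTNCKLGQCVRFDMFLHATYYLEEW
TNPVYFIGCFSENDWNSFPRHWEKPMDHRGNAGAQMWWPRTFFYYIPHQLAFESPFNMYATFDKIWCPNL
YQEQACLDGPAHWPHACEYLRSAVGMRIPPANRFAAYLNGKHSTTINHGFKSGSQIINIGTWMESYDMAR
RTLGLPQNMWQYIRRLIRHQSEKICARWWS
>syn015
MKTDDKDTCYTQNATCSLTYQIIMGHLLKAYPDLDFYSMYNQNVRVTNCKLGQCVRDDMWLHATFYFEEY
TNHVFFIGCWSENDYNSFPRHWEKPMDHRGNAGAQMLWPRTFFYYIPHQHMFNSKFNMYRTFDKYWTLNH
YQEQRCLDGKAHWPIACEYLRSAVGMRIPPANRFAAYLNDKCSTEINHGFKSGSQIINIETWMEDYDMAR
RTKGLPQNMTQYIRALIRHQSEKICARWWS
>syn016
MKTDDKDTCYTQNATCSLTYQIIMGHLLKAYPDLDFYGMPVQNVRVTNCKLGQDVRFDMYLHATFTLEEW
TNPVFFIGCYSENDWNSFPRHWIKPMDHRGNYGAQMWWGRTFFYYIPHQSAFESTFNMYNTFDKIGCLSS
YQEQTCLDGNAHWPIACEYLRSAVGMRIPPANRFFAYLNQKCSTHINHGQKSGSQIINIQTWMEGYDMAR
RTLGLPQNMLQYIRALIRHQSEKICARIWS
>syn017
MKTDDKDTCYTQNATCSGTYQIIMGHLLKAYPDLMFYSMPSQNVRVTNCKLGQCVRFDMALHATGYLEES
TNPVGFIGCASENDSNSFPRHWEKPMDHRGNAGAQMWWPRTFFYYIPHQTAFESVFNMYLTFDKIWCLNT
AQEQVCLKGLAHWPIACEYLRSAVGMRIPPANRFWAYLHIKCSTCINHGFKSGSQIINIITWMECYDMAR
RTKGLPQNMWQMIRALIRHISEKICARWWS
>syn018
MKTDDKDTCYTQNATCSLTYQIIMGHLLKAYPDLDFYSMPSQNVRVTNCKLGQCVRFDIELHATDYLMEQ
TNPVDFIGCESENDQNSFPRHWEKPMDHRGNAGAQMWWPRTFFYYIWHQNAFESKFNMYRTFDKRWCLNN
YQEQRCLDGKAHWPIACEYLRSAVGMRIPPANRFAAYLNHKCSTSINHGFKSGSQIINIHTWMETRDMAR
RTKGLPQNMWQYIRALIRHQSEKICARWWS
>syn019
MKTDDKDTCYTQNATCSLTYQIIMGHLLKAYPDLDFYSMPSQNVSVTNCKLGQCVRFTMCLHATSYLEET
TNPVSFIGCCSENDTNSFPKHWEKPMDHRGNAGAQMWAPRTFFYYIPHQAAFESGFNMYPTFDKIWLLNA
YQEQGCLDGPAHWPIACEDLRSAVGMRIPPANRFAAYLNVKFSTMINHGFKSGSQRINIVTWMEMYDMAR
RTKGLPQNMWQYIRALIRHQSEKICARWWS
>syn020
MQTDDKDDEYTQNAPGSLMYQIIYGHHLKSYQDKDLYCAPSKNVRVTNCKLFQCVPFDMSLECTTYLEKN
KNPVTFIGWSSENDNNRWARVYICRMDHRWMVGAWMYKPITFFYKIYHQQMFMSAFNMYGTFLFKEKLNQ
YQEQACLDGGASFPSQCTYLNQAVGWRIPPANRFKPYLNCKSSLYITHGFKSGFCIINMCTSMEWHDMAR
RQKGLPQKMWQYIYPSIKHQEDKEDARWWN
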