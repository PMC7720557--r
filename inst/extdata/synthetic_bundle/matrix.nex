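#NEXUS
BEGIN DATA;
  DIMENSIONS NTAX=32 NCHAR=131;
  FORMAT DATATYPE=STANDARD SYMBOLS="0123456789" MISSING=? GAP=-;
  MATRIX
    fossil_01  ?0021111411?11001??101??1?0010001?0?120004002120?11????01?1?11??0100?011?10011011?1?10?00010110?0?01110110?0??00101??113?2210003000
    fossil_02  ?002101??1??1?01??010?0?100??001??00140????02?10000100101??1212?020000111?001?11111?2010001?11?201??110?110000?0?0?33??32221000?00?
    fossil_03  01021??02111?10?10??011110?0?000??00140?0?102110100?11111400?12102???11??0??1?1?11???0??12101?0??1?110?010101000???3??13?2????00?00
    fossil_04  ?111?1?001?100111010000100?10?000100?20003?121000011?0?0?30021????40001112?0110?1?102111011?11011200110?010011??101?2???22001030000
    fossil_05  0011???00?01?111???0?0?101?10001?10002?10011?1?0101??110?30011?01320?0111211111010??1?1??111?0122????10?0110?1??101221?32210?0?000?
    fossil_06  ??1?001001???0111?1?0001000000010100?2000401?10?1011??101300210012400?1??211?1001?10111110?110?220?0?101?000010010122?132?1010??000
    fossil_07  0???01?1010??00???1001?1010110000111020?0?112??000?1111??3??01?002000????0??1111110??000??1111032?10100??00111101?1?22??22??1??301?
    fossil_08  10?1?1?10011?0110?1??1?011?110?1?1?102?112?1?10?11110??0?30?210013??00111211?10?1000?01???1?1????300?10101?01???10122?13121?10?0001
    fossil_09  1012?0??0?0?10??1?1?1101?1?00?0000?0120111?11101?0010?000?01110011?30?1??11?10?101010?11001010?1020?1?001?1?0010101?2110??2122200??
    fossil_10  ?0?010?0010?111?10?101?1??11??1?1?00110114?13120?00101010100211?04?0011?12?010111?111??0?0?10?1??011???110110001110??013?21???20?00
    fossil_11  1112?100010111101001000?10110?00?10?1??114?13?2?0?1?00?001010?100?20??1101?0100?01?11?210011??12?201?100110?001110121?13221110?0000
    fossil_12  1010?1?1011110?0?0?0?10?1010100?00?10?000?111?10100101?0010121100?400011?2110?1011??2?1?01???102020?11001111??0?101???132?10?0003??
    fossil_13  110?111?011?1100?00001??0?0010?0?110020?01112?101001??0?010?1??0?300?0111??1?1011000?010??00101012?0110??0?0?1101?133?1?21102???02?
    fossil_14  ?0000??00110?000?000?1??0100010?01111??001011100?011?101??112000?3000010121011?1??00?020?0101??3?31?1101101?1010111?2113211?20300?0
    fossil_15  0100??010?101000100?0100100101?0??10021001111??000?101010?012?00???0011012110101010000?0?01??00?0010110?011000?0111??113?1?120?0020
    fossil_16  110?010???10110?1?000?0?????010000?00200?1011?00?00101?10401?0??1300001??210110??0?0001?10101013001?0101??1010?011132?1??11??03?020
    fossil_17  001200???1101001??01001??011?0?0110102?10210?1201??10100?01110??1?100??01?1001???0000120100??11211?01?00101010??0113??13?31123?0?20
    fossil_18  0010?0?0011?1?0?10010?1?0011?000??010201?110?1?1?011??00100?100?10?0011?010001100010011002001112120?1?01111?000?0013211?2?12?300020
    fossil_19  ?011?00?0??01??010???1110?10100100010?0?0?1?1111?200?10????1100002100110110?0110?0?0211?0100101?02?00?00???00001?0134?112?2?21?0?20
    fossil_20  0110010?0?12?101021?00011?1000?0111002?00???1?2010011?10??0111001?1000101?10111???002??1?200??132100??1?1?01101011?3?01?21?32000000
    fossil_21  ?1021001111210010011011?0111100?11???311?2??11?0?00101??000111?0112001?01111??1?100?1?101200?101?200000?00010101111??0??2112220000?
    fossil_22  11121001??12?00??01101111??0?000?11?03??0?00?11??0?00????0012?211?2000?001??111011000?1?12?00???2??010?100?101?111123????01222?0?00
    fossil_23  1101??011?12110?0?110?110?1110?0?1?00311?21011?010010?0?1001210?1?200??01????11010?00?101200010012?00001010?01?1?1??30032112?200?00
    fossil_24  11?1??001???1001101100110111?000011??3?10200?10000????01001?11101?4?1?0??111110?100?1?2012000????1001?00?001010?111??0??21?2223000?
    fossil_25  10120?10?1??1111001000??01???01000011100?31?012111111001?0012?2010??000?1?011?1010100?211?10?0032??000??1?110?1?101320?32112?3000?0
    fossil_26  0?1200112?12?01?00?00101?00100100??1?1?0?3?00020121111100?012??010?00001110011?010100021?010?1022?0001?011010?10?0122?132110?00002?
    extant_01  ?110100?2?12100??0??11010010001?1??1?2100311?10000??0?010??0212?00?00?001?101?1?1110?0?1020?100122000001?001110?11131?132110??200?0
    fossil_27  1??201?1410210100010000??00001?0??01111??3?00?2011111011000???201???0??111?11?10100000?100100?032?0?0?001011?0101?132?13?110?000?2?
    fossil_28  101?00?1?112110?0??00?010?0010??000?111?0310012?110?0??10001???11130000?111111?01??0012???000001?300?0?101?0???01??22013211?12?202?
    fossil_29  1?0001001?0211?1?011011???11100?011??300?40011?1101100???0?02?1111?0011?011?1?0??00?2???02?00??10?001?011111110?11130013?112?3000?0
    fossil_30  0??00?00001?11?1100?010?010010000?11020??4??11?01?01000101?0?0200210??101????1?1111001?00000?01320??10001011100?1113211321112??00?0
    fossil_31  ?11010110112?1?110??11010010?00?00110?10?1?12?10?01????0?1110?1113?000101211?1?01??01???1000??1??20111??100?0?01??112113?1112000?2?
  ;
END;
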