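# Two-channel filter banks for the twelve supported wavelet functions:
# Daubechies (db1, db3, db5), Coiflets (coif1, coif3, coif5), biorthogonal
# spline (bior3.1, bior3.3, bior3.5) and symlets (sym2, sym4, sym6).
# Standard published coefficients; all four filters of a bank share one
# length L and satisfy the perfect-reconstruction identity
#   conv(rec_lo, dec_lo) + conv(rec_hi, dec_hi) = 2 * z^-(L-1).

.wavelet_filters <- list(
  `db1` = list(
    dec_lo = c(0.7071067811865476, 0.7071067811865476),
    dec_hi = c(-0.7071067811865476, 0.7071067811865476),
    rec_lo = c(0.7071067811865476, 0.7071067811865476),
    rec_hi = c(0.7071067811865476, -0.7071067811865476)
  ),
  `db3` = list(
    dec_lo = c(0.03522629188570953, -0.08544127388202666, -0.13501102001025458,
               0.45987750211849154, 0.8068915093110925, 0.33267055295008263),
    dec_hi = c(-0.33267055295008263, 0.8068915093110925, -0.45987750211849154,
               -0.13501102001025458, 0.08544127388202666, 0.03522629188570953),
    rec_lo = c(0.33267055295008263, 0.8068915093110925, 0.45987750211849154,
               -0.13501102001025458, -0.08544127388202666, 0.03522629188570953),
    rec_hi = c(0.03522629188570953, 0.08544127388202666, -0.13501102001025458,
               -0.45987750211849154, 0.8068915093110925, -0.33267055295008263)
  ),
  `db5` = list(
    dec_lo = c(0.0033357252854737712, -0.012580751999081999, -0.006241490212798274,
               0.07757149384004572, -0.032244869584638375, -0.24229488706638203,
               0.13842814590132074, 0.7243085284377729, 0.6038292697971896,
               0.16010239797419293),
    dec_hi = c(-0.16010239797419293, 0.6038292697971896, -0.7243085284377729,
               0.13842814590132074, 0.24229488706638203, -0.032244869584638375,
               -0.07757149384004572, -0.006241490212798274, 0.012580751999081999,
               0.0033357252854737712),
    rec_lo = c(0.16010239797419293, 0.6038292697971896, 0.7243085284377729,
               0.13842814590132074, -0.24229488706638203, -0.032244869584638375,
               0.07757149384004572, -0.006241490212798274, -0.012580751999081999,
               0.0033357252854737712),
    rec_hi = c(0.0033357252854737712, 0.012580751999081999, -0.006241490212798274,
               -0.07757149384004572, -0.032244869584638375, 0.24229488706638203,
               0.13842814590132074, -0.7243085284377729, 0.6038292697971896,
               -0.16010239797419293)
  ),
  `coif1` = list(
    dec_lo = c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
               0.8525720202116004, 0.3378976624574818, -0.07273261951252645),
    dec_hi = c(0.07273261951252645, 0.3378976624574818, -0.8525720202116004,
               0.3848648468648578, 0.07273261951252645, -0.015655728135791993),
    rec_lo = c(-0.07273261951252645, 0.3378976624574818, 0.8525720202116004,
               0.3848648468648578, -0.07273261951252645, -0.015655728135791993),
    rec_hi = c(-0.015655728135791993, 0.07273261951252645, 0.3848648468648578,
               -0.8525720202116004, 0.3378976624574818, 0.07273261951252645)
  ),
  `coif3` = list(
    dec_lo = c(-3.459977319727278e-05, -7.0983302506379e-05, 0.0004662169598204029,
               0.0011175187708306303, -0.0025745176881367972, -0.009007976136730624,
               0.015880544863669452, 0.03455502757329774, -0.08230192710629983,
               -0.07179982161915484, 0.42848347637737, 0.7937772226260872,
               0.40517690240911824, -0.06112339000297255, -0.06577191128146936,
               0.023452696142077168, 0.007782596425672746, -0.003793512864380802),
    dec_hi = c(0.003793512864380802, 0.007782596425672746, -0.023452696142077168,
               -0.06577191128146936, 0.06112339000297255, 0.40517690240911824,
               -0.7937772226260872, 0.42848347637737, 0.07179982161915484,
               -0.08230192710629983, -0.03455502757329774, 0.015880544863669452,
               0.009007976136730624, -0.0025745176881367972, -0.0011175187708306303,
               0.0004662169598204029, 7.0983302506379e-05, -3.459977319727278e-05),
    rec_lo = c(-0.003793512864380802, 0.007782596425672746, 0.023452696142077168,
               -0.06577191128146936, -0.06112339000297255, 0.40517690240911824,
               0.7937772226260872, 0.42848347637737, -0.07179982161915484,
               -0.08230192710629983, 0.03455502757329774, 0.015880544863669452,
               -0.009007976136730624, -0.0025745176881367972, 0.0011175187708306303,
               0.0004662169598204029, -7.0983302506379e-05, -3.459977319727278e-05),
    rec_hi = c(-3.459977319727278e-05, 7.0983302506379e-05, 0.0004662169598204029,
               -0.0011175187708306303, -0.0025745176881367972, 0.009007976136730624,
               0.015880544863669452, -0.03455502757329774, -0.08230192710629983,
               0.07179982161915484, 0.42848347637737, -0.7937772226260872,
               0.40517690240911824, 0.06112339000297255, -0.06577191128146936,
               -0.023452696142077168, 0.007782596425672746, 0.003793512864380802)
  ),
  `coif5` = list(
    dec_lo = c(-9.604010112767894e-08, -1.6237995172048338e-07, 2.0612203985788783e-06,
               3.7007277113394796e-06, -2.1270221672515614e-05, -4.12198619242655e-05,
               0.00014035632812373243, 0.0003018579416682448, -0.0006375589261258812,
               -0.0016616273039298788, 0.0024315754425382886, 0.006761520220620417,
               -0.009159507338676163, -0.019758391600965465, 0.032674799467057355,
               0.041287530472117834, -0.10556315130733723, -0.06203775157498196,
               0.4379823066591634, 0.7742936228603274, 0.42157126673075435,
               -0.052046670253554764, -0.09192158806008609, 0.028169744270532353,
               0.023408322118927783, -0.010131584846900276, -0.00415931262757864,
               0.0021782943778456947, 0.0003585777411617577, -0.000212081862067494),
    dec_hi = c(0.000212081862067494, 0.0003585777411617577, -0.0021782943778456947,
               -0.00415931262757864, 0.010131584846900276, 0.023408322118927783,
               -0.028169744270532353, -0.09192158806008609, 0.052046670253554764,
               0.42157126673075435, -0.7742936228603274, 0.4379823066591634,
               0.06203775157498196, -0.10556315130733723, -0.041287530472117834,
               0.032674799467057355, 0.019758391600965465, -0.009159507338676163,
               -0.006761520220620417, 0.0024315754425382886, 0.0016616273039298788,
               -0.0006375589261258812, -0.0003018579416682448, 0.00014035632812373243,
               4.12198619242655e-05, -2.1270221672515614e-05, -3.7007277113394796e-06,
               2.0612203985788783e-06, 1.6237995172048338e-07, -9.604010112767894e-08),
    rec_lo = c(-0.000212081862067494, 0.0003585777411617577, 0.0021782943778456947,
               -0.00415931262757864, -0.010131584846900276, 0.023408322118927783,
               0.028169744270532353, -0.09192158806008609, -0.052046670253554764,
               0.42157126673075435, 0.7742936228603274, 0.4379823066591634,
               -0.06203775157498196, -0.10556315130733723, 0.041287530472117834,
               0.032674799467057355, -0.019758391600965465, -0.009159507338676163,
               0.006761520220620417, 0.0024315754425382886, -0.0016616273039298788,
               -0.0006375589261258812, 0.0003018579416682448, 0.00014035632812373243,
               -4.12198619242655e-05, -2.1270221672515614e-05, 3.7007277113394796e-06,
               2.0612203985788783e-06, -1.6237995172048338e-07, -9.604010112767894e-08),
    rec_hi = c(-9.604010112767894e-08, 1.6237995172048338e-07, 2.0612203985788783e-06,
               -3.7007277113394796e-06, -2.1270221672515614e-05, 4.12198619242655e-05,
               0.00014035632812373243, -0.0003018579416682448, -0.0006375589261258812,
               0.0016616273039298788, 0.0024315754425382886, -0.006761520220620417,
               -0.009159507338676163, 0.019758391600965465, 0.032674799467057355,
               -0.041287530472117834, -0.10556315130733723, 0.06203775157498196,
               0.4379823066591634, -0.7742936228603274, 0.42157126673075435,
               0.052046670253554764, -0.09192158806008609, -0.028169744270532353,
               0.023408322118927783, 0.010131584846900276, -0.00415931262757864,
               -0.0021782943778456947, 0.0003585777411617577, 0.000212081862067494)
  ),
  `bior3.1` = list(
    dec_lo = c(-0.3535533905932738, 1.0606601717798212, 1.0606601717798212,
               -0.3535533905932738),
    dec_hi = c(-0.1767766952966369, 0.5303300858899106, -0.5303300858899106,
               0.1767766952966369),
    rec_lo = c(0.1767766952966369, 0.5303300858899106, 0.5303300858899106,
               0.1767766952966369),
    rec_hi = c(-0.3535533905932738, -1.0606601717798212, 1.0606601717798212,
               0.3535533905932738)
  ),
  `bior3.3` = list(
    dec_lo = c(0.06629126073623882, -0.1988737822087165, -0.15467960838455727,
               0.9943689110435825, 0.9943689110435825, -0.15467960838455727,
               -0.1988737822087165, 0.06629126073623882),
    dec_hi = c(0, 0, -0.1767766952966369, 0.5303300858899106,
               -0.5303300858899106, 0.1767766952966369, 0, 0),
    rec_lo = c(0, 0, 0.1767766952966369, 0.5303300858899106,
               0.5303300858899106, 0.1767766952966369, 0, 0),
    rec_hi = c(0.06629126073623882, 0.1988737822087165, -0.15467960838455727,
               -0.9943689110435825, 0.9943689110435825, 0.15467960838455727,
               -0.1988737822087165, -0.06629126073623882)
  ),
  `bior3.5` = list(
    dec_lo = c(-0.013810679320049757, 0.04143203796014927, 0.052480581416189075,
               -0.26792717880896527, -0.07181553246425873, 0.966747552403483,
               0.966747552403483, -0.07181553246425873, -0.26792717880896527,
               0.052480581416189075, 0.04143203796014927, -0.013810679320049757),
    dec_hi = c(0, 0, 0, 0, -0.1767766952966369, 0.5303300858899106,
               -0.5303300858899106, 0.1767766952966369, 0, 0, 0, 0),
    rec_lo = c(0, 0, 0, 0, 0.1767766952966369, 0.5303300858899106,
               0.5303300858899106, 0.1767766952966369, 0, 0, 0, 0),
    rec_hi = c(-0.013810679320049757, -0.04143203796014927, 0.052480581416189075,
               0.26792717880896527, -0.07181553246425873, -0.966747552403483,
               0.966747552403483, 0.07181553246425873, -0.26792717880896527,
               -0.052480581416189075, 0.04143203796014927, 0.013810679320049757)
  ),
  `sym2` = list(
    dec_lo = c(-0.12940952255092145, 0.22414386804185735, 0.836516303737469,
               0.48296291314469025),
    dec_hi = c(-0.48296291314469025, 0.836516303737469, -0.22414386804185735,
               -0.12940952255092145),
    rec_lo = c(0.48296291314469025, 0.836516303737469, 0.22414386804185735,
               -0.12940952255092145),
    rec_hi = c(-0.12940952255092145, -0.22414386804185735, 0.836516303737469,
               -0.48296291314469025)
  ),
  `sym4` = list(
    dec_lo = c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
               0.8037387518059161, 0.29785779560527736, -0.09921954357684722,
               -0.012603967262037833, 0.0322231006040427),
    dec_hi = c(-0.0322231006040427, -0.012603967262037833, 0.09921954357684722,
               0.29785779560527736, -0.8037387518059161, 0.49761866763201545,
               0.02963552764599851, -0.07576571478927333),
    rec_lo = c(0.0322231006040427, -0.012603967262037833, -0.09921954357684722,
               0.29785779560527736, 0.8037387518059161, 0.49761866763201545,
               -0.02963552764599851, -0.07576571478927333),
    rec_hi = c(-0.07576571478927333, 0.02963552764599851, 0.49761866763201545,
               -0.8037387518059161, 0.29785779560527736, 0.09921954357684722,
               -0.012603967262037833, -0.0322231006040427)
  ),
  `sym6` = list(
    dec_lo = c(0.015404109327027373, 0.0034907120842174702, -0.11799011114819057,
               -0.048311742585633, 0.4910559419267466, 0.787641141030194,
               0.3379294217276218, -0.07263752278646252, -0.021060292512300564,
               0.04472490177066578, 0.0017677118642428036, -0.007800708325034148),
    dec_hi = c(0.007800708325034148, 0.0017677118642428036, -0.04472490177066578,
               -0.021060292512300564, 0.07263752278646252, 0.3379294217276218,
               -0.787641141030194, 0.4910559419267466, 0.048311742585633,
               -0.11799011114819057, -0.0034907120842174702, 0.015404109327027373),
    rec_lo = c(-0.007800708325034148, 0.0017677118642428036, 0.04472490177066578,
               -0.021060292512300564, -0.07263752278646252, 0.3379294217276218,
               0.787641141030194, 0.4910559419267466, -0.048311742585633,
               -0.11799011114819057, 0.0034907120842174702, 0.015404109327027373),
    rec_hi = c(0.015404109327027373, -0.0034907120842174702, -0.11799011114819057,
               0.048311742585633, 0.4910559419267466, -0.787641141030194,
               0.3379294217276218, 0.07263752278646252, -0.021060292512300564,
               -0.04472490177066578, 0.0017677118642428036, 0.007800708325034148)
  )
)

#' Supported wavelet functions
#'
#' The twelve wavelet functions available for the stationary wavelet
#' transform: three members each of the Daubechies, Coiflet, biorthogonal
#' spline and symlet families.
#'
#' @return Character vector of the twelve wavelet names.
#' @export
#' @examples
#' wavelet_names()
wavelet_names <- function() names(.wavelet_filters)

.get_filters <- function(wavelet) {
  fb <- .wavelet_filters[[wavelet]]
  if (is.null(fb)) {
    stop("unknown wavelet '", wavelet, "'; valid names are: ",
         paste(wavelet_names(), collapse = ", "), call. = FALSE)
  }
  fb
}
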